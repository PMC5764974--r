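#' Build a common-peak table from per-sample peak lists
#'
#' Groups peaks across samples by greedy nearest-retention-time matching.
#' Peaks from all samples are pooled and scanned in retention-time order; a
#' peak joins the current group while it lies within `rt_tol` minutes of the
#' group's running median retention time, otherwise it starts a new group.
#' Only groups containing exactly one peak from *every* sample become common
#' peaks; groups with two peaks of one sample inside the window are rejected
#' (retention-time collision) and reported, not silently dropped.
#'
#' @param chroms Either a long data frame with columns `sample_id`, `rt`,
#'   `area`, or a named list of per-sample data frames with columns `rt`,
#'   `area` (retention times strictly increasing within a sample, areas
#'   non-negative).
#' @param rt_tol Retention-time tolerance in minutes (> 0), default 0.5.
#' @return An object of class `common_peak_table`: list with `areas`
#'   (samples x peaks matrix), `rts` (consensus retention time per peak,
#'   the median of member rts), `sample_ids`, `peak_ids`, and `rejected`
#'   (data frame of non-common groups with a reason).
#' @export
match_common_peaks <- function(chroms, rt_tol = 0.5) {
  stopifnot(rt_tol > 0)
  if (is.data.frame(chroms)) {
    stopifnot(all(c("sample_id", "rt", "area") %in% names(chroms)))
    long <- chroms[c("sample_id", "rt", "area")]
    long$sample_id <- as.character(long$sample_id)
  } else {
    stopifnot(is.list(chroms), !is.null(names(chroms)))
    long <- do.call(rbind, lapply(names(chroms), function(s) {
      d <- chroms[[s]]
      data.frame(sample_id = s, rt = d$rt, area = d$area)
    }))
  }
  samples <- unique(long$sample_id)
  if (length(samples) < 2L) stop("need at least 2 chromatograms")
  stopifnot(all(long$area >= 0), all(is.finite(long$rt)))
  for (s in samples) {
    rts <- long$rt[long$sample_id == s]
    if (is.unsorted(rts, strictly = TRUE)) {
      stop("retention times must be strictly increasing within sample '",
           s, "'")
    }
  }

  ord <- order(long$rt)
  long <- long[ord, ]
  group <- integer(nrow(long))
  g <- 0L
  members <- numeric(0) # rts of current group
  for (i in seq_len(nrow(long))) {
    if (g == 0L || abs(long$rt[i] - stats::median(members)) > rt_tol) {
      g <- g + 1L
      members <- long$rt[i]
    } else {
      members <- c(members, long$rt[i])
    }
    group[i] <- g
  }

  peaks <- list()
  rejected <- list()
  for (gi in seq_len(g)) {
    rows <- long[group == gi, ]
    rt_med <- stats::median(rows$rt)
    if (anyDuplicated(rows$sample_id)) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        rt = rt_med, n_members = nrow(rows),
        reason = "rt collision: multiple peaks of one sample in group")
    } else if (!setequal(rows$sample_id, samples)) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        rt = rt_med, n_members = nrow(rows),
        reason = "not present in all samples")
    } else {
      peaks[[length(peaks) + 1L]] <-
        list(rt = rt_med, area = stats::setNames(rows$area, rows$sample_id))
    }
  }

  areas <- matrix(0, nrow = length(samples), ncol = length(peaks),
                  dimnames = list(samples,
                                  if (length(peaks)) seq_along(peaks)))
  for (j in seq_along(peaks)) areas[, j] <- peaks[[j]]$area[samples]
  common_peak_table(
    areas,
    rts = vapply(peaks, `[[`, numeric(1), "rt"),
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(rt = numeric(0), n_members = integer(0),
                 reason = character(0)))
}

#' Construct a common-peak table
#'
#' @param areas Numeric samples x peaks matrix, non-negative, no missing
#'   cells (a common peak is by definition present in every sample).
#' @param rts Optional consensus retention time per peak (minutes).
#' @param rejected Optional data frame of rejected peak groups.
#' @return Object of class `common_peak_table`.
#' @export
common_peak_table <- function(areas, rts = NULL, rejected = NULL) {
  areas <- as.matrix(areas)
  stopifnot(is.numeric(areas), !anyNA(areas), all(areas >= 0))
  if (is.null(rownames(areas))) rownames(areas) <- paste0("S", seq_len(nrow(areas)))
  if (is.null(colnames(areas))) colnames(areas) <- as.character(seq_len(ncol(areas)))
  if (!is.null(rts)) stopifnot(length(rts) == ncol(areas))
  structure(list(areas = areas, rts = rts,
                 sample_ids = rownames(areas), peak_ids = colnames(areas),
                 rejected = rejected),
            class = "common_peak_table")
}

#' @export
print.common_peak_table <- function(x, ...) {
  cat("Common-peak table:", nrow(x$areas), "samples x", ncol(x$areas),
      "common peaks\n")
  if (!is.null(x$rts)) {
    cat("  consensus rt (min):",
        paste(formatC(x$rts, format = "f", digits = 2), collapse = ", "), "\n")
  }
  if (!is.null(x$rejected) && nrow(x$rejected) > 0) {
    cat("  rejected groups:", nrow(x$rejected), "\n")
  }
  invisible(x)
}

#' Median reference fingerprint
#'
#' The simulated reference chromatogram of a batch of fingerprints: the
#' per-peak median of areas across samples ("median method").
#'
#' @param t A `common_peak_table`.
#' @return Named numeric vector, one entry per common peak.
#' @export
reference_fingerprint <- function(t) {
  stopifnot(inherits(t, "common_peak_table"), ncol(t$areas) >= 1)
  apply(t$areas, 2L, stats::median)
}

#' Cosine (congruence) similarity between two fingerprints
#'
#' @param u,v Numeric vectors of equal length; neither may be all zeros.
#' @return `u.v / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 1,
            is.finite(u), is.finite(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for a zero vector")
  }
  sum(u * v) / (nu * nv)
}

#' Batch similarity evaluation against the median reference
#'
#' Computes each sample's cosine similarity with the median reference
#' fingerprint, plus the full pairwise sample-sample similarity matrix.
#'
#' @param t A `common_peak_table` with at least 2 samples.
#' @return Object of class `similarity_report`: `reference` (median
#'   fingerprint), `per_sample` (named vector of similarities vs the
#'   reference), `pairwise` (matrix).
#' @export
similarity_report <- function(t) {
  stopifnot(inherits(t, "common_peak_table"), nrow(t$areas) >= 2)
  ref <- reference_fingerprint(t)
  per <- apply(t$areas, 1L, cosine_similarity, v = ref)
  n <- nrow(t$areas)
  pw <- matrix(1, n, n, dimnames = list(t$sample_ids, t$sample_ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pw[i, j] <- pw[j, i] <- cosine_similarity(t$areas[i, ], t$areas[j, ])
    }
  }
  structure(list(reference = ref, per_sample = per, pairwise = pw),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, digits = 3, ...) {
  rng <- range(x$per_sample)
  cat("Fingerprint similarity vs median reference (",
      length(x$per_sample), " samples)\n", sep = "")
  cat("  range: ", formatC(rng[1], format = "f", digits = digits), "-",
      formatC(rng[2], format = "f", digits = digits), "\n", sep = "")
  print(round(x$per_sample, digits), ...)
  invisible(x)
}
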