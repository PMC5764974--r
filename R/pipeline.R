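#' Pipeline configuration
#'
#' Collects every tunable threshold of the marker-screening pipeline with
#' the published defaults: VIP threshold 1.0, equivalence limits
#' (0.70, 1.43), BP-ANN with 3 hidden knots trained 5000 epochs, MIV
#' perturbation +/-10%.
#'
#' @param vip_threshold VIP screening threshold (1.0).
#' @param ncomp PLS components; `NULL` = leave-one-out CV choice.
#' @param hidden,epochs,lr,momentum BP-ANN settings; the pipeline default
#'   learning rate is 0.02 — at 5000 epochs it limits how much of the
#'   endpoint noise the network absorbs, which stabilises the MIV ranking.
#' @param restarts Independently initialised networks averaged for the MIV
#'   stage (5); see [miv_ensemble()].
#' @param delta MIV perturbation fraction (0.10).
#' @param metric,linkage Clustering settings.
#' @param alpha,limits Equivalence test settings.
#' @param seed Integer seed used for the BP-ANN initialisation.
#' @return Object of class `hecm_config` (a list).
#' @export
hecm_config <- function(vip_threshold = 1.0, ncomp = NULL, hidden = 3L,
                        epochs = 5000L, lr = 0.02, momentum = 0.9,
                        restarts = 5L, delta = 0.10, metric = "euclidean",
                        linkage = "average", alpha = 0.10,
                        limits = c(0.70, 1.43), seed = 1L) {
  structure(as.list(environment()), class = "hecm_config")
}

#' Run the full marker-screening pipeline
#'
#' Orchestrates the four-step strategy on a common-peak table and matching
#' toxicity data: (1) similarity evaluation of the fingerprints; (2) PLS
#' regression of per-sample mean ALT/AST on peak areas with VIP screening;
#' (3) BP-ANN training with mean-impact-value ranking; (4) hierarchical
#' clustering of peaks together with the enzyme endpoints. The final marker
#' set is the intersection of the VIP-selected peaks and the top-k peaks by
#' MIV with k equal to the VIP selection size (cluster co-membership with
#' ALT/AST is reported as supporting evidence, not used as a gate). When
#' per-animal data for a candidate marker combination and the original
#' extract are supplied, the equivalence stage is run per enzyme.
#'
#' @param peaks A [common_peak_table()] (or samples x peaks matrix).
#' @param toxicity A `toxicity_table` from [generate_toxicity()], or a long
#'   data frame with columns `sample_id`, `ALT`, `AST` (per animal; means
#'   are taken per sample).
#' @param config A [hecm_config()].
#' @param equivalence Optional list with elements `candidate` and
#'   `original`, each a numeric vector (one enzyme) or a data frame with
#'   columns `ALT` and `AST` of per-animal values.
#' @return Object of class `hecm_report`.
#' @export
hecm_pipeline <- function(peaks, toxicity, config = hecm_config(),
                          equivalence = NULL) {
  stopifnot(inherits(config, "hecm_config"))
  if (!inherits(peaks, "common_peak_table")) peaks <- common_peak_table(peaks)
  if (inherits(toxicity, "toxicity_table")) {
    tox_means <- toxicity$group_means
  } else {
    stopifnot(is.data.frame(toxicity),
              all(c("sample_id", "ALT", "AST") %in% names(toxicity)))
    tox_means <- cbind(
      ALT = tapply(toxicity$ALT, toxicity$sample_id, mean),
      AST = tapply(toxicity$AST, toxicity$sample_id, mean))
  }
  missing_ids <- setdiff(peaks$sample_ids, rownames(tox_means))
  extra_ids <- setdiff(rownames(tox_means), peaks$sample_ids)
  if (length(missing_ids) || length(extra_ids)) {
    stop("sample ids do not align between peak and toxicity tables; ",
         "missing toxicity for: ",
         paste(missing_ids, collapse = ", "), "; unmatched toxicity ids: ",
         paste(extra_ids, collapse = ", "))
  }
  Y <- tox_means[peaks$sample_ids, c("ALT", "AST"), drop = FALSE]
  X <- peaks$areas

  sim <- similarity_report(peaks)
  pls <- pls_fit(X, Y, ncomp = config$ncomp)
  vip_res <- vip(pls, threshold = config$vip_threshold)
  ann <- train_bpann(X, Y, hidden = config$hidden, epochs = config$epochs,
                     lr = config$lr, momentum = config$momentum,
                     seed = config$seed)
  miv_res <- if (config$restarts > 1L) {
    miv_ensemble(X, Y, restarts = config$restarts, delta = config$delta,
                 hidden = config$hidden, epochs = config$epochs,
                 lr = config$lr, momentum = config$momentum,
                 seed = config$seed)
  } else {
    miv(ann, X, delta = config$delta)
  }
  hm <- heatmap_matrix(peaks, Y, metric = config$metric,
                       linkage = config$linkage)

  vip_sel <- vip_res$selected
  k <- max(length(vip_sel), 0L)
  miv_top <- if (k > 0) rank_variables(miv_res, top_k = k) else character(0)
  selected <- intersect(vip_sel, miv_top)

  eq <- NULL
  if (!is.null(equivalence)) {
    stopifnot(is.list(equivalence),
              all(c("candidate", "original") %in% names(equivalence)))
    cand <- equivalence$candidate; orig <- equivalence$original
    if (is.data.frame(cand)) {
      eq <- lapply(intersect(colnames(cand), c("ALT", "AST")), function(enz) {
        equivalence_test(cand[[enz]], orig[[enz]], alpha = config$alpha,
                         limits = config$limits)
      })
      names(eq) <- intersect(colnames(cand), c("ALT", "AST"))
    } else {
      eq <- list(equivalence_test(cand, orig, alpha = config$alpha,
                                  limits = config$limits))
    }
  }

  structure(list(similarity = sim, pls = pls, vip = vip_res, ann = ann,
                 miv = miv_res, heatmap = hm,
                 vip_selected = vip_sel, miv_top = miv_top,
                 selected_markers = selected, equivalence = eq,
                 config = config, sample_ids = peaks$sample_ids,
                 peak_ids = peaks$peak_ids),
            class = "hecm_report")
}

#' @export
print.hecm_report <- function(x, ...) {
  cat("== HECM screening report ==\n")
  rng <- range(x$similarity$per_sample)
  cat("Fingerprints: ", length(x$sample_ids), " samples x ",
      length(x$peak_ids), " common peaks; similarity vs reference ",
      formatC(rng[1], format = "f", digits = 3), "-",
      formatC(rng[2], format = "f", digits = 3), "\n", sep = "")
  cat("PLS: ", x$pls$ncomp, " component(s), R^2 = ",
      formatC(x$pls$r_squared, format = "f", digits = 3), "\n", sep = "")
  cat("VIP > ", x$vip$threshold, ": ",
      paste(x$vip_selected, collapse = ", "), "\n", sep = "")
  cat("MIV top-", length(x$miv_top), ": ",
      paste(x$miv_top, collapse = ", "), "\n", sep = "")
  cat("Selected markers: ",
      if (length(x$selected_markers))
        paste(x$selected_markers, collapse = ", ") else "(none)", "\n",
      sep = "")
  if (!is.null(x$equivalence)) {
    for (enz in names(x$equivalence)) {
      e <- x$equivalence[[enz]]
      cat("Equivalence [", enz, "]: ", equivalence_decision(e)$report,
          " -> ", if (e$equivalent) "equivalent" else "not equivalent",
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' Writes the quantitative content of an [hecm_pipeline()] report (per-peak
#' VIP and MIV, similarity summary, selections, equivalence CIs, and the
#' configuration) as JSON; the result parses back losslessly with
#' [jsonlite::fromJSON()].
#'
#' @param report An `hecm_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "hecm_report"))
  payload <- list(
    samples = report$sample_ids,
    peaks = report$peak_ids,
    similarity = list(range = range(report$similarity$per_sample),
                      per_sample = report$similarity$per_sample),
    pls = list(ncomp = report$pls$ncomp, r_squared = report$pls$r_squared,
               adjusted_r_squared = report$vip$adjusted_r_squared),
    vip = as.list(report$vip$vip),
    miv = as.list(report$miv$miv),
    vip_selected = report$vip_selected,
    miv_top = report$miv_top,
    selected_markers = report$selected_markers,
    equivalence = if (is.null(report$equivalence)) NULL else
      lapply(report$equivalence, function(e)
        list(ci = e$ratio_ci, limits = e$limits, sigma_w = e$sigma_w,
             df = e$df, equivalent = e$equivalent)),
    config = unclass(report$config))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
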