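# Monoisotopic masses (Da) of the most abundant isotope, CODATA/IUPAC 2021
# atomic mass evaluation; >= 7 decimal places.
.ISOTOPE_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  O  = 15.9949146221,
  N  = 14.0030740052,
  Cl = 34.9688527100,
  S  = 31.9720706900,
  P  = 30.9737619800,
  Na = 22.9897692800,
  K  = 38.9637064900
)

# CODATA electron mass in Da; negative-mode ions carry one extra electron.
.ELECTRON_MASS <- 0.0005485799

# Negative-mode adduct deltas (Da), electron mass included.
# [M+COOH]- is the formate adduct [M+HCOO]-: delta = mass(CHO2) + m_e.
.ADDUCTS <- list(
  "[M-H]-"    = list(delta = -(1.0078250319) + 0.0005485799, charge = -1L),
  "[M+Cl]-"   = list(delta = 34.9688527100 + 0.0005485799, charge = -1L),
  "[M+COOH]-" = list(delta = 12.0 + 1.0078250319 + 2 * 15.9949146221 +
                       0.0005485799, charge = -1L)
)

#' Supported negative-mode adducts
#'
#' @return A data frame with one row per supported adduct: its name, the
#'   signed mass delta in Da (electron mass included) and the charge.
#' @export
#' @examples
#' adducts()
adducts <- function() {
  data.frame(
    name = names(.ADDUCTS),
    mass_delta = vapply(.ADDUCTS, `[[`, numeric(1), "delta"),
    charge = vapply(.ADDUCTS, `[[`, integer(1), "charge"),
    row.names = NULL
  )
}

#' Parse a molecular formula
#'
#' Parses an elemental formula such as `"C15H10O7"` into a named vector of
#' element counts. Underscores used as visual separators (`"C_12_H_22_O_11"`)
#' are ignored. The grammar is deliberately small: element symbols followed by
#' an optional integer count; no parentheses, isotope labels or charges.
#' Repeated mentions of an element are summed.
#'
#' @param text Formula string. The empty string parses to an empty count
#'   vector (mass 0).
#' @return Named integer vector of element counts (class `element_counts`).
#' @export
#' @examples
#' parse_formula("C15H10O7")
#' parse_formula("C_12_H_22_O_11")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("_", "", text, fixed = TRUE)
  counts <- integer(0)
  if (nzchar(s)) {
    m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
    tokens <- regmatches(s, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(s)) {
      bad <- substr(gsub("[A-Z][a-z]?[0-9]*", "", s), 1L, 8L)
      stop("cannot parse formula '", text, "': unexpected token '", bad, "'")
    }
    for (tok in tokens) {
      el <- gsub("[0-9]+$", "", tok)
      if (!el %in% names(.ISOTOPE_MASS)) {
        stop("unknown element symbol '", el, "' in formula '", text, "'")
      }
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
    }
  }
  structure(counts, class = "element_counts")
}

#' Canonical Hill-order formula string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; count 1
#' is implicit. `parse_formula(formula_string(x))` reproduces `x`.
#'
#' @param counts Element counts from [parse_formula()] (or a named vector).
#' @return A single string.
#' @export
formula_string <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return("")
  els <- names(counts)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  paste0(vapply(ord, function(el) {
    n <- counts[[el]]
    paste0(el, if (n > 1L) n else "")
  }, character(1)), collapse = "")
}

#' @export
print.element_counts <- function(x, ...) {
  cat("<element_counts>", formula_string(x), "\n")
  invisible(x)
}

.as_counts <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) > 0) {
    stopifnot(!is.null(names(f)), all(names(f) %in% names(.ISOTOPE_MASS)),
              all(f >= 0))
  }
  f
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count x most-abundant-isotope mass over the elements of the
#' formula. The empty formula has mass 0.
#'
#' @param f Formula string or element counts.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C15H10O7") # 302.042653
monoisotopic_mass <- function(f) {
  f <- .as_counts(f)
  if (length(f) == 0L) return(0)
  sum(.ISOTOPE_MASS[names(f)] * as.numeric(f))
}

#' Theoretical adduct m/z
#'
#' m/z of a singly charged negative-mode ion: the neutral monoisotopic mass
#' plus the adduct delta, which includes the mass of the extra electron.
#' Rounded to 4 decimals this reproduces the calculated m/z column of the
#' packaged compound library (see [dbt_peak_library()]).
#'
#' @param f Formula string or element counts (non-empty).
#' @param adduct One of `"[M-H]-"`, `"[M+Cl]-"`, `"[M+COOH]-"`.
#' @return Theoretical m/z in Da.
#' @export
#' @examples
#' adduct_mz("C15H10O7", "[M-H]-")     # quercetin, 301.0354
#' adduct_mz("C19H20O6", "[M+COOH]-")  # diosbulbin B, 389.1242
adduct_mz <- function(f, adduct) {
  if (!adduct %in% names(.ADDUCTS)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  }
  m <- monoisotopic_mass(f)
  if (m <= 0) stop("adduct m/z requires a non-empty formula")
  m + .ADDUCTS[[adduct]]$delta
}

#' Mass error in parts per million
#'
#' `(calculated - experimental) / calculated * 1e6`.
#'
#' @param calculated Theoretical m/z (> 0).
#' @param experimental Observed m/z.
#' @return Signed error in ppm.
#' @export
ppm_error <- function(calculated, experimental) {
  if (any(calculated <= 0)) stop("calculated m/z must be positive")
  (calculated - experimental) / calculated * 1e6
}

#' Annotate observed peaks against a compound library
#'
#' Matches each observed m/z to every library ion whose theoretical m/z lies
#' within `tol_ppm`. Unmatched peaks are kept and flagged, not dropped;
#' multiple hits are all reported, ordered by absolute ppm error.
#'
#' @param observed Data frame with columns `peak_id`, `rt`, `mz`.
#' @param library Data frame with columns `formula`, `adduct` and `name`
#'   (plus any others, carried through), e.g. [dbt_peak_library()].
#' @param tol_ppm Match tolerance in ppm (> 0), default 5.
#' @return Data frame with one row per (peak, hit) pair; unmatched peaks get
#'   a single row with `matched = FALSE`.
#' @export
annotate_peaks <- function(observed, library, tol_ppm = 5) {
  stopifnot(is.data.frame(observed),
            all(c("peak_id", "rt", "mz") %in% names(observed)))
  if (!is.data.frame(library) || nrow(library) == 0L) {
    stop("annotation library is empty")
  }
  stopifnot(all(c("formula", "adduct", "name") %in% names(library)),
            tol_ppm > 0)
  lib_mz <- mapply(function(f, a) adduct_mz(f, a),
                   library$formula, library$adduct)
  out <- lapply(seq_len(nrow(observed)), function(i) {
    err <- ppm_error(lib_mz, observed$mz[i])
    hit <- which(abs(err) <= tol_ppm)
    if (length(hit) == 0L) {
      data.frame(peak_id = observed$peak_id[i], rt = observed$rt[i],
                 mz = observed$mz[i], matched = FALSE, name = NA_character_,
                 formula = NA_character_, adduct = NA_character_,
                 calculated_mz = NA_real_, error_ppm = NA_real_)
    } else {
      hit <- hit[order(abs(err[hit]))]
      data.frame(peak_id = observed$peak_id[i], rt = observed$rt[i],
                 mz = observed$mz[i], matched = TRUE,
                 name = library$name[hit], formula = library$formula[hit],
                 adduct = library$adduct[hit], calculated_mz = lib_mz[hit],
                 error_ppm = err[hit])
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Packaged DBT compound library
#'
#' The 40 constituents characterised in *Dioscorea bulbifera* tuber extract
#' by negative-mode UHPLC-QTOF MS: retention time, proposed molecular
#' formula, detected adduct, experimental m/z and, as printed in the source
#' table, the calculated m/z and ppm error. Theoretical m/z values can be
#' recomputed from the formulas with [adduct_mz()].
#'
#' @return Data frame with columns `peak_no`, `rt_min`, `formula`, `adduct`,
#'   `experimental_mz`, `calculated_mz`, `error_ppm`, `name`.
#' @export
dbt_peak_library <- function() {
  path <- system.file("extdata", "dbt_peak_library.csv",
                      package = "hecmscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
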