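# Deterministic assay arithmetic: LDH-release percent cytotoxicity and
# receptor-selectivity KD/EC50 ratio tables with NB/WB sentinel handling.

#' Percent cytotoxicity from LDH-release measurements
#'
#' \deqn{\%Cytotoxicity = \frac{experimental - spont._{effector} -
#'   spont._{target}}{maximum_{target} - spont._{target}} \times 100}
#' All four terms are LDH signals (absorbance). Values may fall below 0 or
#' exceed 100 (signalled with a warning but reported as-is).
#'
#' @param experimental experimental lysis signal
#' @param spont_effector spontaneous effector-cell lysis
#' @param spont_target spontaneous target-cell lysis
#' @param max_target maximum (detergent) target lysis
#' @return percentage(s)
#' @export
percent_cytotoxicity <- function(experimental, spont_effector, spont_target,
                                 max_target) {
  denom <- max_target - spont_target
  if (any(denom <= 0))
    stop("maximum target lysis must exceed spontaneous target lysis")
  val <- (experimental - spont_effector - spont_target) / denom * 100
  if (any(val < 0 | val > 100))
    warning("percent cytotoxicity outside [0, 100] for ",
            sum(val < 0 | val > 100), " measurement(s)")
  val
}

# Affinity values are numerics or the sentinels NB (no measurable binding)
# and WB (weak binding); parse from the printed string form.
is_sentinel <- function(x) {
  is.character(x) & toupper(trimws(x)) %in% c("NB", "WB")
}

affinity_value <- function(x) {
  if (is.numeric(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  v[is_sentinel(x)] <- NA_real_
  v
}

#' Selectivity ratio of two affinity values
#'
#' Ratio of two KDs (or EC50s) for the same variant, rounded half-up at the
#' table's printed precision. Any sentinel operand (`"NB"`, `"WB"`) gives an
#' undefined ratio (`NA`), rendered `"/"` in formatted tables.
#'
#' @param numerator,denominator KD values in mol/L, numeric or the printed
#'   string form (scientific notation, `"NB"` or `"WB"`)
#' @param decimals decimal places of the printed table (default 2)
#' @return rounded numeric ratio, or `NA` when undefined
#' @export
selectivity_ratio <- function(numerator, denominator, decimals = 2L) {
  num <- affinity_value(numerator)
  den <- affinity_value(denominator)
  out <- ifelse(is.na(num) | is.na(den) | den == 0, NA_real_,
                round_half_up(num / den, decimals))
  unname(out)
}

#' Read a delimited affinity panel
#'
#' Long-format tab-delimited file with columns `variant`, `receptor`,
#' `value`; values are KDs in mol/L in scientific notation or the sentinels
#' `NB` / `WB`.
#'
#' @param path TSV path
#' @return data.frame with character `value` column
#' @export
read_affinity_panel <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("variant", "receptor", "value") %in% names(x)))
  x
}

#' Receptor-selectivity ratio table
#'
#' One row per variant, one ratio column per (numerator receptor,
#' denominator receptor) pair, reproducing the ratio columns of printed KD
#' tables. Sentinel-valued cells give `"/"`; missing measurements give `NA`.
#'
#' @param records affinity panel: data.frame with `variant`, `receptor`,
#'   `value` (value numeric or printed string with NB/WB sentinels)
#' @param pairs list of length-2 character vectors
#'   `c(numerator receptor, denominator receptor)`
#' @param decimals printed decimal places (default 2)
#' @param formatted return printed strings (`"0.39"`, `"/"`) instead of
#'   numeric ratios (default `TRUE`)
#' @return data.frame: `variant` plus one column per pair (named
#'   `"num/den"`), variants in first-appearance order
#' @export
ratio_table <- function(records, pairs, decimals = 2L, formatted = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("variant", "receptor", "value") %in% names(records)))
  variants <- unique(records$variant)
  out <- data.frame(variant = variants, stringsAsFactors = FALSE)
  lookup <- function(variant, receptor) {
    hit <- records$value[records$variant == variant &
                           records$receptor == receptor]
    if (length(hit) == 0L) NA_character_ else as.character(hit[1L])
  }
  for (p in pairs) {
    stopifnot(length(p) == 2L)
    vals <- vapply(variants, function(v) {
      num <- lookup(v, p[1L]); den <- lookup(v, p[2L])
      if (is.na(num) || is.na(den)) return(NA_real_)
      selectivity_ratio(num, den, decimals)
    }, numeric(1L))
    sentinel <- vapply(variants, function(v) {
      num <- lookup(v, p[1L]); den <- lookup(v, p[2L])
      (!is.na(num) && is_sentinel(num)) || (!is.na(den) && is_sentinel(den))
    }, logical(1L))
    col <- paste0(p[1L], "/", p[2L])
    if (formatted) {
      txt <- formatC(vals, format = "f", digits = decimals)
      txt[is.na(vals)] <- NA_character_
      txt[sentinel] <- "/"
      out[[col]] <- txt
    } else {
      out[[col]] <- vals
    }
  }
  rownames(out) <- NULL
  out
}
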