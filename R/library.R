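# Two-position degenerate Fc library definitions: variant-space enumeration,
# theoretical diversity, transformant coverage, and degenerate oligo design.

#' Define a degenerate Fc loop library
#'
#' A library diversifies two positions at a time (each with all 20 amino
#' acids) within one interface loop. Positions are named by EU numbers and
#' mapped onto codons of the sequenced variable region through
#' `codon_index`.
#'
#' @param name library name
#' @param positions data.frame with columns `eu` (EU residue number), `wt_aa`
#'   (wild-type one-letter amino acid) and `codon_index` (1-based codon in
#'   `ref_dna`)
#' @param ref_dna wild-type DNA of the sequenced variable region; length
#'   divisible by 3 and translating (frame +1) to a peptide whose residues at
#'   `codon_index` equal `wt_aa`
#' @param up_flank,down_flank constant DNA immediately up/downstream of the
#'   variable region in each read
#' @param barcode_fwd,barcode_rev sample barcodes (forward barcode is
#'   prepended to reads)
#' @param codon_scheme degenerate codon used at diversified positions
#'   (default `"NNK"`, the 32-codon scheme covering all 20 amino acids)
#' @return an object of class `fc_library`
#' @export
fc_library <- function(name, positions, ref_dna, up_flank, down_flank,
                       barcode_fwd, barcode_rev = "", codon_scheme = "NNK") {
  stopifnot(is.data.frame(positions),
            all(c("eu", "wt_aa", "codon_index") %in% names(positions)))
  positions <- positions[order(positions$eu), , drop = FALSE]
  rownames(positions) <- NULL
  if (anyDuplicated(positions$eu)) stop("duplicated EU positions")
  ref_dna <- toupper(ref_dna)
  if (nchar(ref_dna) %% 3L != 0L)
    stop("reference DNA length must be divisible by 3")
  pep <- translate_dna(ref_dna)
  n_codons <- nchar(ref_dna) / 3L
  if (any(positions$codon_index < 1L | positions$codon_index > n_codons))
    stop("codon_index outside the reference")
  ref_aa <- substring(pep, positions$codon_index, positions$codon_index)
  if (!all(ref_aa == positions$wt_aa))
    stop("reference does not translate to the stated wild-type residues at ",
         paste(positions$eu[ref_aa != positions$wt_aa], collapse = ", "))
  if (!nzchar(barcode_fwd)) stop("forward barcode must be non-empty")
  structure(list(
    name = name, positions = positions, ref_dna = ref_dna,
    up_flank = toupper(up_flank), down_flank = toupper(down_flank),
    barcode_fwd = toupper(barcode_fwd), barcode_rev = toupper(barcode_rev),
    codon_scheme = toupper(codon_scheme)
  ), class = "fc_library")
}

#' @export
print.fc_library <- function(x, ...) {
  cat("fc_library '", x$name, "': ", nrow(x$positions),
      " loop positions (EU ", paste(x$positions$eu, collapse = ", "),
      "), scheme ", x$codon_scheme, "\n", sep = "")
  invisible(x)
}

#' Read a library definition from a YAML config
#'
#' Expected keys: `name`, `positions` (list of maps with `eu`, `wt`,
#' `codon`), `ref_dna`, `up_flank`, `down_flank`, `barcode_fwd`,
#' optional `barcode_rev` and `codon_scheme`.
#'
#' @param path YAML file path
#' @return an `fc_library`
#' @export
read_library_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pos <- do.call(rbind, lapply(cfg$positions, function(p)
    data.frame(eu = as.integer(p$eu), wt_aa = p$wt,
               codon_index = as.integer(p$codon), stringsAsFactors = FALSE)))
  fc_library(
    name = cfg$name, positions = pos, ref_dna = cfg$ref_dna,
    up_flank = cfg$up_flank, down_flank = cfg$down_flank,
    barcode_fwd = cfg$barcode_fwd,
    barcode_rev = if (is.null(cfg$barcode_rev)) "" else cfg$barcode_rev,
    codon_scheme = if (is.null(cfg$codon_scheme)) "NNK" else cfg$codon_scheme
  )
}

#' Parse a variant display string into substitutions
#'
#' `"H268E/K326M/I332E"` becomes a data.frame of (EU position, from, to);
#' `"WT"` becomes an empty data.frame.
#'
#' @param spec a single display string in the standard slash-separated
#'   notation
#' @return data.frame with columns `eu`, `from`, `to`, sorted by `eu`
#' @export
parse_variant_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  if (spec == "WT" || spec == "")
    return(data.frame(eu = integer(0), from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(spec, "/", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([A-Y])([0-9]+)([A-Y])$", parts))
  if (any(lengths(m) != 4L)) stop("malformed variant spec: ", spec)
  out <- data.frame(
    eu = as.integer(vapply(m, `[`, "", 3L)),
    from = vapply(m, `[`, "", 2L),
    to = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$eu), , drop = FALSE]
  if (anyDuplicated(out$eu)) stop("duplicated position in spec: ", spec)
  if (any(out$from == out$to)) stop("from == to in spec: ", spec)
  rownames(out) <- NULL
  out
}

#' Format substitutions as a variant display string
#'
#' Inverse of [parse_variant_spec()]: ascending EU position, slash-separated;
#' zero substitutions formats as `"WT"`.
#'
#' @param subs data.frame with columns `eu`, `from`, `to`
#' @return display string
#' @export
format_variant_spec <- function(subs) {
  if (nrow(subs) == 0L) return("WT")
  subs <- subs[order(subs$eu), , drop = FALSE]
  paste0(subs$from, subs$eu, subs$to, collapse = "/")
}

#' Enumerate the designed variant space of a library
#'
#' Every unordered pair of loop positions receives every 20 x 20 amino-acid
#' assignment. Assignments equal to wild type at a position drop that
#' substitution from the spec, so single mutants and the wild type itself are
#' members of the space.
#'
#' @param lib an `fc_library` with at least 2 loop positions
#' @param dedup collapse to distinct amino-acid sequences over the loop
#'   (default `FALSE`: the raw design enumeration, one row per
#'   pair x assignment)
#' @return data.frame with columns `spec` (display string), `loop_aa`
#'   (amino-acid string over the loop positions, EU order) and `n_sub`
#' @export
enumerate_variants <- function(lib, dedup = FALSE) {
  stopifnot(inherits(lib, "fc_library"))
  pos <- lib$positions
  L <- nrow(pos)
  if (L < 2L) stop("library must have at least 2 loop positions")
  pairs <- utils::combn(L, 2L)
  wt_loop <- pos$wt_aa

  grids <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    g <- expand.grid(aa_i = AA20, aa_j = AA20, stringsAsFactors = FALSE)
    loop <- matrix(rep(wt_loop, each = nrow(g)), nrow = nrow(g))
    loop[, i] <- g$aa_i
    loop[, j] <- g$aa_j
    data.frame(
      loop_aa = apply(loop, 1L, paste0, collapse = ""),
      i = i, j = j, aa_i = g$aa_i, aa_j = g$aa_j,
      stringsAsFactors = FALSE
    )
  })
  all <- do.call(rbind, grids)

  spec_of <- function(i, j, aa_i, aa_j) {
    parts <- character(0)
    if (aa_i != wt_loop[i]) parts <- c(parts, paste0(wt_loop[i], pos$eu[i], aa_i))
    if (aa_j != wt_loop[j]) parts <- c(parts, paste0(wt_loop[j], pos$eu[j], aa_j))
    if (length(parts) == 0L) "WT" else paste(parts, collapse = "/")
  }
  all$spec <- mapply(spec_of, all$i, all$j, all$aa_i, all$aa_j,
                     USE.NAMES = FALSE)
  all$n_sub <- (all$aa_i != wt_loop[all$i]) + (all$aa_j != wt_loop[all$j])
  out <- all[, c("spec", "loop_aa", "n_sub")]
  if (dedup) {
    out <- out[!duplicated(out$loop_aa), , drop = FALSE]
    out <- out[order(out$loop_aa), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Theoretical diversity of a two-position library
#'
#' The raw design count is \eqn{\binom{L}{2} \cdot 20^2} for a loop of
#' length L (every position pair, every amino-acid assignment). With
#' `dedup = TRUE` the deduplicated count of distinct amino-acid sequences is
#' returned instead (wild-type-matching assignments collapse across pairs).
#'
#' @param lib an `fc_library`
#' @param dedup return the distinct amino-acid-sequence count
#' @return integer diversity
#' @export
theoretical_diversity <- function(lib, dedup = FALSE) {
  stopifnot(inherits(lib, "fc_library"))
  L <- nrow(lib$positions)
  if (L < 2L) stop("library must have at least 2 loop positions")
  if (!dedup) return(as.integer(choose(L, 2L) * 400L))
  nrow(enumerate_variants(lib, dedup = TRUE))
}

#' Expected library coverage from a transformant count
#'
#' The expected fraction of a variant space of size D represented among T
#' uniform independent transformants: \eqn{1 - (1 - 1/D)^T}. A 10-fold
#' excess of transformants over the theoretical diversity gives at least 95%
#' expected coverage for any D (in fact > 99.99%).
#'
#' @param D theoretical diversity (>= 1)
#' @param T_transformants number of transformants (>= 0)
#' @return expected covered fraction in [0, 1]
#' @export
expected_coverage <- function(D, T_transformants) {
  stopifnot(all(D >= 1), all(T_transformants >= 0))
  # log-space for numerical stability at large T
  -expm1(T_transformants * log1p(-1 / D))
}

#' Transformants needed for a target expected coverage
#'
#' Minimal T with `expected_coverage(D, T) >= p`, i.e.
#' \eqn{\lceil \ln(1-p) / \ln(1-1/D) \rceil}.
#'
#' @param D theoretical diversity (>= 1)
#' @param p target coverage in (0, 1)
#' @return integer transformant count
#' @export
transformants_for_coverage <- function(D, p) {
  stopifnot(all(D >= 1))
  if (any(p <= 0 | p >= 1)) stop("target coverage must lie in (0, 1)")
  ifelse(D == 1, 1L, as.integer(ceiling(log1p(-p) / log1p(-1 / D))))
}

# Degenerate-codon expansions for supported schemes.
scheme_codons <- function(scheme) {
  switch(toupper(scheme),
    NNK = nnk_codons(),
    stop("unsupported codon scheme: ", scheme)
  )
}

#' Degenerate oligo diversifying one position pair
#'
#' Returns the reference variable-region DNA with the codons of the two
#' targeted EU positions replaced by the library's degenerate codon (default
#' NNK); all other codons are untouched.
#'
#' @param lib an `fc_library`
#' @param pair two distinct EU positions, both in the library's loop
#' @return nucleotide string with IUPAC degenerate codes at the two codons
#' @export
degenerate_oligo <- function(lib, pair) {
  stopifnot(inherits(lib, "fc_library"), length(pair) == 2L)
  if (pair[1L] == pair[2L])
    stop("a degenerate oligo diversifies two distinct positions")
  idx <- match(pair, lib$positions$eu)
  if (anyNA(idx)) stop("position(s) not in the loop: ",
                       paste(pair[is.na(idx)], collapse = ", "))
  codons <- substring(lib$ref_dna,
                      seq(1L, nchar(lib$ref_dna), by = 3L),
                      seq(3L, nchar(lib$ref_dna), by = 3L))
  codons[lib$positions$codon_index[idx]] <- lib$codon_scheme
  paste0(codons, collapse = "")
}
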