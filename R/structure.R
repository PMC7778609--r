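# Interface-residue identification on Fc/FcgammaR complex structures.
#
# Candidate mutagenesis positions are the Fc residues with any heavy atom
# within a distance cutoff (default 5 Angstrom) of the receptor chains, as in
# structure-guided loop-library design on complexes such as Fc/FcgammaRIIIa
# (PDB 3SGJ) and Fc/FcgammaRIIb (PDB 3WJJ).

#' Load a PDB structure into an atom table
#'
#' Parses ATOM (and optionally HETATM) records into a flat atom table.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties: first encountered), so every atom position is represented once.
#'
#' @param path path to a PDB file
#' @param include_het keep HETATM records (waters, glycans)? Default `FALSE`:
#'   interface criteria are defined on protein residues.
#' @return an object of class `fc_structure`: a list with element `atoms`, a
#'   data.frame with columns `chain`, `resno` (author numbering), `insert`,
#'   `resid` (3-letter), `elety` (atom name), `elesy` (element), `x`, `y`,
#'   `z`, `o` (occupancy), `type` ("ATOM"/"HETATM")
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  GLY A   1      0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  ALA B   1      4.000   0.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' load_structure(pdb)
#' @export
load_structure <- function(path, include_het = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not parseable as PDB: ", path, " (",
                             conditionMessage(e), ")")
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM records in ", path)
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)

  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1

  # altLoc resolution: per (chain, residue, atom name) keep the conformer with
  # the highest occupancy; ties broken by file order.
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert, at$eleno), , drop = FALSE]

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety, elesy = toupper(trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z, o = at$o, type = at$type,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms, source = path), class = "fc_structure")
}

#' @export
print.fc_structure <- function(x, ...) {
  a <- x$atoms
  nres <- length(unique(paste(a$chain, a$resno, a$insert)))
  cat("fc_structure:", nrow(a), "atoms,", nres, "residues, chains",
      paste(sort(unique(a$chain)), collapse = " "), "\n")
  invisible(x)
}

#' Residues of one binding partner within a distance cutoff of the other
#'
#' A query-chain residue is reported iff at least one of its retained atoms
#' lies within `cutoff` Angstrom of any retained atom of a partner chain.
#' By default only heavy atoms enter the distance search (crystal structures
#' typically lack hydrogens anyway).
#'
#' @param model an `fc_structure` from [load_structure()]
#' @param query_chains chain ids whose residues are reported (e.g. the Fc
#'   chains)
#' @param partner_chains chain ids of the binding partner (e.g. the receptor)
#' @param cutoff contact distance in Angstrom (default 5.0)
#' @param heavy_atoms_only exclude hydrogens from the search (default `TRUE`)
#' @return data.frame with one row per contacting query residue, sorted by
#'   (chain, residue number, insertion code): columns `chain`, `resno`,
#'   `insert`, `resid`, `min_distance_A`
#' @export
interface_positions <- function(model, query_chains, partner_chains,
                                cutoff = 5.0, heavy_atoms_only = TRUE) {
  stopifnot(inherits(model, "fc_structure"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive distance in Angstrom")
  if (length(intersect(query_chains, partner_chains)) > 0L)
    stop("query and partner chain sets must be disjoint")
  a <- model$atoms
  have <- unique(a$chain)
  missing <- setdiff(c(query_chains, partner_chains), have)
  if (length(missing) > 0L)
    stop("chain(s) not present in structure: ", paste(missing, collapse = ", "))
  if (heavy_atoms_only) a <- a[a$elesy != "H" & a$elesy != "D", , drop = FALSE]

  q <- a[a$chain %in% query_chains, , drop = FALSE]
  p <- a[a$chain %in% partner_chains, , drop = FALSE]
  if (nrow(q) == 0L || nrow(p) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      min_distance_A = numeric(0), stringsAsFactors = FALSE))

  # all-pairs squared distances query x partner, blocked over query atoms to
  # bound memory on large complexes
  pmat <- cbind(p$x, p$y, p$z)
  mind2 <- numeric(nrow(q))
  block <- 2000L
  for (s in seq(1L, nrow(q), by = block)) {
    e <- min(s + block - 1L, nrow(q))
    qm <- cbind(q$x[s:e], q$y[s:e], q$z[s:e])
    d2 <- outer(rowSums(qm^2), rowSums(pmat^2), "+") - 2 * tcrossprod(qm, pmat)
    mind2[s:e] <- apply(d2, 1L, min)
  }
  mind2[mind2 < 0] <- 0  # numerical guard

  key <- paste(q$chain, q$resno, q$insert, sep = "\r")
  res_min <- tapply(sqrt(mind2), key, min)
  first <- !duplicated(key)
  info <- q[first, c("chain", "resno", "insert", "resid")]
  info$min_distance_A <- as.numeric(res_min[paste(info$chain, info$resno,
                                                  info$insert, sep = "\r")])
  out <- info[info$min_distance_A <= cutoff, , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group contacting residues into contiguous loops
#'
#' Consecutive residue numbers (within one chain) whose gaps do not exceed
#' `max_gap` are merged into one loop; loops are ordered by first residue.
#'
#' @param positions data.frame as returned by [interface_positions()]
#'   (columns `chain`, `resno`)
#' @param max_gap largest residue-number gap bridged within one loop
#'   (default 1, i.e. directly consecutive or one missing residue)
#' @return list of data.frames, one per loop
#' @export
group_loops <- function(positions, max_gap = 1L) {
  stopifnot(is.data.frame(positions), all(c("chain", "resno") %in% names(positions)))
  if (nrow(positions) == 0L) return(list())
  positions <- positions[order(positions$chain, positions$resno), , drop = FALSE]
  newgrp <- c(TRUE, diff(positions$resno) > max_gap |
                positions$chain[-1L] != positions$chain[-nrow(positions)])
  grp <- cumsum(newgrp)
  out <- split(positions, grp)
  names(out) <- NULL
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
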