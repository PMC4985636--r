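#' Inter-chain residue contacts under an any-atom distance criterion
#'
#' A peptide residue and a domain residue are in contact when any two of
#' their atoms (hydrogens included, if present in the file) lie strictly
#' closer than `cutoff` angstroms. This is the criterion used to define the
#' per-position binding pockets that the pair-potential score is summed
#' over.
#'
#' @param structure A `ptb_structure` from [parse_pdb()].
#' @param cutoff Distance cutoff in angstroms; default 4.5. Pairs at exactly
#'   the cutoff are excluded (strict `<`).
#' @return A `ptb_contacts` tibble: one row per contacting residue pair with
#'   columns `pep_chain, pep_resno, pep_insert, pep_aa, dom_chain,
#'   dom_resno, dom_insert, dom_aa, min_dist`. Attributes: `cutoff` and
#'   `peptide_residues` (the full ordered peptide residue table, so empty
#'   pockets can be reconstructed downstream).
#' @export
compute_contacts <- function(structure, cutoff = 4.5) {
  stopifnot(inherits(structure, "ptb_structure"), cutoff > 0)
  at <- structure$atoms
  pep <- at[at$role == "peptide", ]
  dom <- at[at$role == "domain", ]
  if (nrow(pep) == 0) {
    abort("structure has an empty peptide partition",
          class = "ptb_error_contract")
  }
  if (nrow(dom) == 0) {
    abort("structure has an empty domain partition",
          class = "ptb_error_contract")
  }
  d <- cross_dist(as.matrix(pep[, c("x", "y", "z")]),
                  as.matrix(dom[, c("x", "y", "z")]))
  pk <- paste(pep$chain, pep$resno, pep$insert)
  dk <- paste(dom$chain, dom$resno, dom$insert)
  ## residue-pair minimum over the atom-pair distance matrix
  long <- tibble(
    pep_key = rep(pk, times = nrow(dom)),
    dom_key = rep(dk, each = nrow(pep)),
    dist = as.vector(d)
  ) |>
    group_by(.data$pep_key, .data$dom_key) |>
    summarise(min_dist = min(.data$dist), .groups = "drop") |>
    filter(.data$min_dist < cutoff)

  pinfo <- distinct(pep, key = pk, pep_chain = .data$chain,
                    pep_resno = .data$resno, pep_insert = .data$insert,
                    pep_aa = .data$aa)
  dinfo <- distinct(dom, key = dk, dom_chain = .data$chain,
                    dom_resno = .data$resno, dom_insert = .data$insert,
                    dom_aa = .data$aa)
  out <- long |>
    left_join(pinfo, by = c(pep_key = "key")) |>
    left_join(dinfo, by = c(dom_key = "key")) |>
    select("pep_chain", "pep_resno", "pep_insert", "pep_aa",
           "dom_chain", "dom_resno", "dom_insert", "dom_aa", "min_dist") |>
    arrange(.data$pep_resno, .data$pep_insert, .data$dom_chain,
            .data$dom_resno, .data$dom_insert)
  attr(out, "cutoff") <- cutoff
  attr(out, "peptide_residues") <- peptide_residues(structure)
  class(out) <- c("ptb_contacts", class(out))
  out
}

cross_dist <- function(a, b) {
  ## pairwise Euclidean distances, rows of a x rows of b
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Per-position binding pockets in the motif frame
#'
#' Re-indexes the peptide residues of a contact map relative to the motif
#' tyrosine (Y = 0, N-terminal flanks negative, matching the Tyr(-5) /
#' Asn(-3) convention) and collects, for every peptide position, the set of
#' contacting domain residues — its binding pocket. Positions without
#' contacts get an empty pocket.
#'
#' @param contacts A `ptb_contacts` from [compute_contacts()].
#' @param y_position 1-based index of the motif tyrosine along the peptide
#'   chain. Default `NULL` locates it with [find_motif()] on the peptide
#'   sequence.
#' @return A `ptb_pockets` object: list with `positions` (tibble: position,
#'   chain, resno, insert, aa — every peptide residue) and `contacts`
#'   (tibble: position, dom_chain, dom_resno, dom_insert, dom_aa, min_dist).
#' @export
build_pockets <- function(contacts, y_position = NULL) {
  stopifnot(inherits(contacts, "ptb_contacts"))
  pep <- attr(contacts, "peptide_residues")
  if (is.null(y_position)) {
    anchor <- find_motif(paste(pep$aa, collapse = ""))
    y_position <- anchor$y_index
  }
  if (y_position < 1 || y_position > nrow(pep)) {
    abort("anchor lies outside the peptide chain",
          class = "ptb_error_contract")
  }
  positions <- pep |>
    mutate(position = row_number() - y_position) |>
    select("position", "chain", "resno", "insert", "aa")
  pocket_contacts <- as_tibble(contacts) |>
    left_join(
      positions |>
        rename(pep_chain = "chain", pep_resno = "resno",
               pep_insert = "insert"),
      by = c("pep_chain", "pep_resno", "pep_insert")
    ) |>
    select("position", "dom_chain", "dom_resno", "dom_insert", "dom_aa",
           "min_dist") |>
    arrange(.data$position, .data$dom_chain, .data$dom_resno)
  structure(list(positions = positions, contacts = pocket_contacts),
            class = "ptb_pockets")
}

#' @export
print.ptb_pockets <- function(x, ...) {
  occ <- unique(x$contacts$position)
  cat("<ptb_pockets> peptide positions ", min(x$positions$position), "..",
      max(x$positions$position), " (Y = 0); ", length(occ),
      " occupied pockets, ", nrow(x$contacts), " contacts\n", sep = "")
  invisible(x)
}

#' Write a contact map (or pocket map) as TSV
#'
#' @param contacts A `ptb_contacts` or `ptb_pockets` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  if (inherits(contacts, "ptb_pockets")) {
    tab <- contacts$contacts |>
      left_join(select(contacts$positions, "position", pep_aa = "aa"),
                by = "position") |>
      select("position", "pep_aa", "dom_chain", "dom_resno", "dom_aa",
             "min_dist")
  } else {
    tab <- as_tibble(contacts)
  }
  readr::write_tsv(tab, path)
  invisible(path)
}
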