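#' Pair-potential score of a threaded peptide
#'
#' The binding score is the sum of contact-potential entries over every
#' (peptide position, domain pocket residue) contact of the template pocket
#' map, with the candidate's residue substituted at each position:
#' \deqn{S = \sum_{i} \sum_{j \in pocket(i)} E(a_i, b_j)}
#' Lower (more negative) scores denote more favorable predicted binding.
#' Template positions the candidate does not cover contribute nothing;
#' pocket contacts come from the template complex and are not recomputed
#' per candidate.
#'
#' @param pockets A `ptb_pockets`.
#' @param peptide A `ptb_threaded` (phosphomimic already applied — a pY
#'   token here is an error).
#' @param matrix A `ptb_matrix`.
#' @return A `ptb_score`: list with `total` and `per_contact` (tibble:
#'   position, pep_aa, dom_chain, dom_resno, dom_aa, energy).
#' @export
score_peptide <- function(pockets, peptide, matrix) {
  stopifnot(inherits(pockets, "ptb_pockets"),
            inherits(peptide, "ptb_threaded"))
  terms <- pockets$contacts |>
    inner_join(peptide$mapping, by = "position")
  if (nrow(terms) == 0) {
    return(structure(list(total = 0,
                          per_contact = tibble(
                            position = integer(), pep_aa = character(),
                            dom_chain = character(), dom_resno = integer(),
                            dom_aa = character(), energy = double())),
                     class = "ptb_score"))
  }
  terms <- terms |>
    mutate(energy = pair_energy(matrix, .data$aa, .data$dom_aa)) |>
    select(position = "position", pep_aa = "aa", "dom_chain", "dom_resno",
           "dom_aa", "energy")
  structure(list(total = sum(terms$energy), per_contact = terms),
            class = "ptb_score")
}

#' @export
print.ptb_score <- function(x, ...) {
  cat("<ptb_score> total ", format(x$total), " over ",
      nrow(x$per_contact), " contact terms\n", sep = "")
  invisible(x)
}

#' @rdname score_peptide
#' @param x A `ptb_score`.
#' @param ... Unused.
#' @method tidy ptb_score
#' @export
tidy.ptb_score <- function(x, ...) x$per_contact

#' @rdname score_peptide
#' @method glance ptb_score
#' @export
glance.ptb_score <- function(x, ...) {
  tibble(total = x$total, n_terms = nrow(x$per_contact))
}
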