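#' Detect hydrogen bonds by donor-acceptor heavy-atom distance
#'
#' Static-structure hydrogen-bond inventory in the style of a
#' domain-peptide interaction diagram: every nitrogen (donor) / oxygen
#' (acceptor) pair from distinct residues, with at least one residue on the
#' peptide chain, is reported as a hydrogen bond when the N...O distance is
#' at most `da_cutoff`. No angular term is applied — only heavy-atom
#' distances are used, so the criterion works on crystal structures without
#' hydrogens. Bonds are labeled `"domain-peptide"` or `"intra-peptide"` and
#' sorted by distance.
#'
#' @param structure A `ptb_structure`.
#' @param da_cutoff Donor-acceptor distance cutoff in angstroms
#'   (default 3.5; inclusive).
#' @return Tibble with one row per bond: donor_chain, donor_resno,
#'   donor_aa, donor_atom, acceptor_chain, acceptor_resno, acceptor_aa,
#'   acceptor_atom, distance, category. May be empty.
#' @export
detect_hbonds <- function(structure, da_cutoff = 3.5) {
  stopifnot(inherits(structure, "ptb_structure"), da_cutoff > 0)
  at <- structure$atoms
  don <- at[at$elesy == "N", ]
  acc <- at[at$elesy == "O", ]
  if (nrow(don) == 0 || nrow(acc) == 0) {
    return(empty_hbonds())
  }
  d <- cross_dist(as.matrix(don[, c("x", "y", "z")]),
                  as.matrix(acc[, c("x", "y", "z")]))
  idx <- which(d <= da_cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(empty_hbonds())
  }
  di <- don[idx[, 1], ]
  ai <- acc[idx[, 2], ]
  out <- tibble(
    donor_chain = di$chain, donor_resno = di$resno, donor_insert = di$insert,
    donor_aa = di$aa, donor_atom = di$elety,
    acceptor_chain = ai$chain, acceptor_resno = ai$resno,
    acceptor_insert = ai$insert, acceptor_aa = ai$aa,
    acceptor_atom = ai$elety,
    distance = d[idx],
    donor_role = di$role, acceptor_role = ai$role
  ) |>
    # exclude intra-residue pairs and domain-domain pairs
    filter(!(.data$donor_chain == .data$acceptor_chain &
               .data$donor_resno == .data$acceptor_resno &
               .data$donor_insert == .data$acceptor_insert),
           .data$donor_role == "peptide" | .data$acceptor_role == "peptide") |>
    mutate(category = ifelse(.data$donor_role == "peptide" &
                               .data$acceptor_role == "peptide",
                             "intra-peptide", "domain-peptide")) |>
    select(-"donor_role", -"acceptor_role", -"donor_insert",
           -"acceptor_insert") |>
    arrange(.data$distance)
  out
}

empty_hbonds <- function() {
  tibble(
    donor_chain = character(), donor_resno = integer(),
    donor_aa = character(), donor_atom = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_aa = character(), acceptor_atom = character(),
    distance = double(), category = character()
  )
}
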