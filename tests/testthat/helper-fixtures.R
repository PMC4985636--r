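# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Format arbitrary atom rows as PDB-fixed-width text. df columns:
# chain, resno, resid, name, x, y, z, element.
write_toy_pdb <- function(df, path, models = NULL) {
  fmt <- function(d) {
    vapply(seq_len(nrow(d)), function(i) {
      sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              i, sprintf(" %-3s", d$name[i]), d$resid[i], d$chain[i],
              d$resno[i], d$x[i], d$y[i], d$z[i], 1, 0, d$element[i])
    }, character(1))
  }
  if (is.null(models)) {
    writeLines(c(fmt(df), "TER", "END"), path)
  } else {
    lines <- character(0)
    for (k in seq_along(models)) {
      lines <- c(lines, sprintf("MODEL     %4d", k), fmt(models[[k]]),
                 "TER", "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

# Minimal domain(2 residues) + peptide(4 residues, NPTY motif) toy with
# single-atom residues placed so that residue-pair distances are obvious.
toy_atoms <- function() {
  tibble::tibble(
    chain = c("A", "A", "B", "B", "B", "B"),
    resno = c(1L, 2L, 1L, 2L, 3L, 4L),
    resid = c("LEU", "VAL", "ASN", "PRO", "THR", "TYR"),
    name = "CA",
    x = c(0, 50, 3, 60, 70, 80),
    y = 0, z = 0,
    element = "C"
  )
}

parse_toy <- function(df = toy_atoms(), ...) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  write_toy_pdb(df, path)
  parse_pdb(path, domain_chains = "A", peptide_chain = "B", ...)
}

# Random small structure for oracle comparisons: every residue gets 1-3
# atoms at random positions in a compact box so distances straddle typical
# cutoffs. Total atom count kept <= 50.
random_toy_structure <- function(seed, n_dom = 4, n_pep = 4) {
  set.seed(seed)
  mk <- function(chain, n, resids) {
    purrr::map(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      tibble::tibble(
        chain = chain, resno = i, resid = resids[i],
        name = c("N", "CA", "CB")[seq_len(k)],
        x = runif(k, 0, 12), y = runif(k, 0, 12), z = runif(k, 0, 12),
        element = c("N", "C", "C")[seq_len(k)]
      )
    }) |> purrr::list_rbind()
  }
  resnames <- names(ptbscreen:::AA3TO1)
  df <- dplyr::bind_rows(
    mk("A", n_dom, sample(resnames, n_dom, replace = TRUE)),
    mk("B", n_pep, sample(resnames, n_pep, replace = TRUE))
  )
  parse_toy(df)
}

# Exhaustive atom-pair scan: the independent oracle for compute_contacts.
brute_force_contacts <- function(structure, cutoff) {
  at <- structure$atoms
  pep <- at[at$role == "peptide", ]
  dom <- at[at$role == "domain", ]
  found <- list()
  for (i in seq_len(nrow(pep))) {
    for (j in seq_len(nrow(dom))) {
      d <- sqrt(sum((c(pep$x[i], pep$y[i], pep$z[i]) -
                       c(dom$x[j], dom$y[j], dom$z[j]))^2))
      if (d < cutoff) {
        key <- paste(pep$chain[i], pep$resno[i], "|", dom$chain[j],
                     dom$resno[j])
        found[[key]] <- min(found[[key]] %||% Inf, d)
      }
    }
  }
  found
}

`%||%` <- rlang::`%||%`

# Pocket map built directly, bypassing geometry, for scoring unit tests.
# contacts: data frame (position, dom_aa); positions inferred.
make_toy_pockets <- function(contacts, positions = NULL,
                             pep_aa = NULL) {
  pos <- positions %||% seq(min(c(contacts$position, 0)) - 1,
                            max(c(contacts$position, 0)) + 1)
  n <- length(pos)
  structure(list(
    positions = tibble::tibble(
      position = pos, chain = "B", resno = seq_len(n), insert = "",
      aa = pep_aa %||% rep("A", n)),
    contacts = tibble::tibble(
      position = contacts$position,
      dom_chain = "A",
      dom_resno = seq_len(nrow(contacts)),
      dom_insert = "",
      dom_aa = contacts$dom_aa,
      min_dist = 4.0)
  ), class = "ptb_pockets")
}

# Template complex emulating a hydrophobic peptide-binding groove: one
# pocket residue for most peptide positions of the 13-mer template.
groove_complex <- function(path, seed = 11) {
  make_complex(
    n_domain_residues = 12, n_peptide_residues = 13,
    contacts = data.frame(pep = c(2, 3, 4, 5, 6, 7, 8, 10, 11, 12),
                          dom = 1:10, distance = 4.0),
    peptide_seq = "QNGYENPTYKFFE", domain_seq = "FILWYVMFLIAR",
    seed = seed, path = path)
}

groove_pockets <- function(seed = 11) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  groove_complex(path, seed = seed)
  s <- parse_pdb(path, "A", "B")
  build_pockets(compute_contacts(s))
}

# Tie-aware Mann-Whitney AUC by exhaustive pair counting: the independent
# oracle for roc_curve()'s trapezoidal AUC.
mann_whitney_auc <- function(scores) {
  b <- scores$score[scores$label == "binder"]
  n <- scores$score[scores$label == "nonbinder"]
  cmp <- outer(b, n, function(x, y) (x < y) + 0.5 * (x == y))
  mean(cmp)
}

table1_panel <- function() {
  readr::read_tsv(system.file("extdata", "x11_affinity_panel.tsv",
                              package = "ptbscreen"),
                  show_col_types = FALSE)
}
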