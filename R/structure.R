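#' Parse a domain-peptide complex from a PDB file
#'
#' Reads a PDB-format structure (via bio3d) and returns the requested chains
#' of the requested model as a tidy atom table partitioned into domain and
#' peptide sides. Waters and unrecognized heteroatoms are dropped;
#' modified residues are renamed through an alias table (by default
#' PTR -> the lowercase pY token `"y"`, SEP -> S, TPO -> T, MSE -> M).
#' Alternate locations other than blank/"A" are discarded.
#'
#' @param path Path to a PDB file.
#' @param domain_chains Character vector of chain identifiers forming the
#'   domain (receptor) side.
#' @param peptide_chain Single chain identifier of the bound peptide.
#' @param model Model number to keep for multi-model (NMR-style) files;
#'   default 1.
#' @param aliases Named character vector mapping nonstandard 3-letter
#'   residue names to one-letter codes (`"y"` allowed for phosphotyrosine).
#' @return A `ptb_structure`: list with `atoms` (tibble: chain, resno,
#'   insert, resid, aa, role, elety, elesy, is_backbone, x, y, z),
#'   `domain_chains`, `peptide_chain`, `model`.
#' @export
parse_pdb <- function(path, domain_chains, peptide_chain, model = 1,
                      aliases = DEFAULT_RESIDUE_ALIASES) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "ptb_error_io")
  }
  validate_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    abort(paste0("model ", model, " requested but file has ", n_models),
          class = "ptb_error_contract")
  }
  at <- as_tibble(pdb$atom)
  ## substitute the requested model's coordinates
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  chains <- unique(c(domain_chains, peptide_chain))
  missing_ch <- setdiff(chains, unique(at$chain))
  if (length(missing_ch) > 0) {
    abort(paste0("chain(s) not present in ", basename(path), ": ",
                 paste(missing_ch, collapse = ", ")),
          class = "ptb_error_chain")
  }
  map <- c(AA3TO1, aliases)
  at <- at |>
    filter(.data$chain %in% chains, .data$resid %in% names(map)) |>
    mutate(
      insert = ifelse(is.na(.data$insert), "", .data$insert),
      aa = unname(map[.data$resid]),
      elesy = ifelse(is.na(.data$elesy) | .data$elesy == "",
                     sub("^[0-9]*([A-Za-z]).*$", "\\1", .data$elety),
                     .data$elesy),
      is_backbone = .data$elety %in% c("N", "CA", "C", "O"),
      role = ifelse(.data$chain == peptide_chain, "peptide", "domain")
    ) |>
    select("chain", "resno", "insert", "resid", "aa", "role",
           "elety", "elesy", "is_backbone", "x", "y", "z")

  if (any(!is.finite(c(at$x, at$y, at$z)))) {
    abort("non-finite atom coordinates", class = "ptb_error_parse")
  }
  structure(
    list(atoms = at, domain_chains = domain_chains,
         peptide_chain = peptide_chain, model = model),
    class = "ptb_structure"
  ) |>
    validate_structure()
}

## Cheap record-level validation so that a malformed coordinate field is
## reported with its line number (bio3d's own errors are opaque).
validate_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  coords <- substr(lines[rec], 31, 54)
  ok <- vapply(coords, function(s) {
    v <- suppressWarnings(as.numeric(c(substr(s, 1, 8), substr(s, 9, 16),
                                       substr(s, 17, 24))))
    !anyNA(v)
  }, logical(1), USE.NAMES = FALSE)
  if (any(!ok)) {
    abort(paste0("unreadable coordinate record at line ",
                 which(rec)[which(!ok)[1]], " of ", basename(path)),
          class = "ptb_error_parse")
  }
  invisible(TRUE)
}

validate_structure <- function(s) {
  pep <- peptide_residues(s)
  if (nrow(pep) < 4) {
    abort("peptide chain must have at least 4 residues (NXXY motif length)",
          class = "ptb_error_contract")
  }
  key <- paste(s$atoms$chain, s$atoms$resno, s$atoms$insert)
  if (nrow(s$atoms) == 0) {
    abort("no atoms after filtering", class = "ptb_error_contract")
  }
  invisible(key) # residues are keyed on (chain, resno, insert)
  s
}

#' Peptide residues of a parsed structure, in chain order
#' @param structure A `ptb_structure`.
#' @return Tibble with one row per peptide residue: chain, resno, insert, aa.
#' @export
peptide_residues <- function(structure) {
  structure$atoms |>
    filter(.data$role == "peptide") |>
    distinct(.data$chain, .data$resno, .data$insert, .data$aa)
}

#' One-letter sequence of the bound peptide
#' @param structure A `ptb_structure`.
#' @return Character scalar; phosphotyrosine appears as lowercase `"y"`.
#' @export
peptide_sequence <- function(structure) {
  paste(peptide_residues(structure)$aa, collapse = "")
}

#' @export
print.ptb_structure <- function(x, ...) {
  pep <- peptide_residues(x)
  cat("<ptb_structure> model ", x$model, ": domain chain(s) ",
      paste(x$domain_chains, collapse = ","), " (",
      sum(x$atoms$role == "domain"), " atoms), peptide chain ",
      x$peptide_chain, " (", nrow(pep), " residues: ",
      paste(pep$aa, collapse = ""), ")\n", sep = "")
  invisible(x)
}
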