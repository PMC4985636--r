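#' Synthetic residue contact pair potential
#'
#' Builds the package's synthetic 20x20 statistical contact potential. It is
#' a deterministic stand-in with the qualitative structure of published
#' residue contact potentials such as the Betancourt-Thirumalai (BT) matrix:
#' symmetric, dimensionless, with hydrophobic-hydrophobic contacts most
#' favorable (most negative), oppositely charged pairs mildly favorable
#' (salt bridges), and like-charged pairs unfavorable. It is *not* a
#' transcription of any published matrix; for production screening supply a
#' published potential to [load_matrix()] in the same file format.
#'
#' The functional form is
#' \deqn{E(a,b) = -0.45\, h_a h_b + 0.30\, q_a q_b}
#' rounded to 3 decimals, where `h` is a burial/hydrophobicity propensity
#' and `q` a formal charge (+1 K/R, +0.5 H, -1 D/E).
#'
#' @return A `ptb_matrix` object: a symmetric 20x20 numeric matrix with
#'   one-letter amino-acid dimnames, plus a `name` attribute.
#' @export
#' @examples
#' m <- synthetic_contact_matrix()
#' m["F", "F"] # most favorable class of contact
#' m["E", "R"] # salt bridge, mildly favorable
synthetic_contact_matrix <- function() {
  h <- c(A = 0.8, R = 0.1, N = 0.0, D = -0.1, C = 1.4, Q = 0.0, E = -0.1,
         G = 0.5, H = 0.6, I = 1.5, L = 1.5, K = -0.3, M = 1.3, F = 1.6,
         P = 0.3, S = 0.3, T = 0.4, W = 1.5, Y = 1.0, V = 1.3)
  q <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0.5,
         I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0,
         Y = 0, V = 0)
  e <- round(-0.45 * outer(h[AA20], h[AA20]) + 0.30 * outer(q[AA20], q[AA20]), 3)
  dimnames(e) <- list(AA20, AA20)
  new_ptb_matrix(e, name = "synthetic")
}

new_ptb_matrix <- function(e, name) {
  stopifnot(is.matrix(e), identical(dim(e), c(20L, 20L)))
  structure(e, name = name, class = c("ptb_matrix", "matrix", "array"))
}

#' Load a residue contact pair-potential matrix
#'
#' Reads a whitespace-delimited pair-potential table with one-letter row and
#' column headers. Either a full 20x20 table or a triangular one (each row
#' carrying entries up to the diagonal) is accepted; triangles are
#' symmetrized by mirroring. All 210 unordered pairs of the 20 standard
#' amino acids must be present.
#'
#' @param path Path to the matrix file. The default is the packaged
#'   synthetic potential (see [synthetic_contact_matrix()]).
#' @return A `ptb_matrix`: symmetric 20x20 numeric matrix, dimnames are
#'   one-letter codes, with lower (more negative) values denoting more
#'   favorable contacts.
#' @export
load_matrix <- function(path = default_matrix_path()) {
  if (!file.exists(path)) {
    abort(paste0("matrix file not found: ", path), class = "ptb_error_io")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  header <- toks[[1]]
  rows <- toks[-1]
  if (!setequal(header, AA20)) {
    abort("matrix header must list the 20 standard one-letter codes",
          class = "ptb_error_asset")
  }
  e <- matrix(NA_real_, 20, 20, dimnames = list(AA20, AA20))
  for (r in rows) {
    aa <- r[[1]]
    vals <- suppressWarnings(as.numeric(r[-1]))
    if (!aa %in% AA20 || anyNA(vals)) {
      abort(paste0("unreadable matrix row for residue '", aa, "'"),
            class = "ptb_error_asset")
    }
    cols <- header[seq_along(vals)]
    e[aa, cols] <- vals
  }
  ## mirror whichever triangle was provided; conflicting duplicates rejected
  tr <- t(e)
  both <- !is.na(e) & !is.na(tr)
  if (any(abs(e[both] - tr[both]) > 1e-9)) {
    abort("matrix is not symmetric", class = "ptb_error_asset")
  }
  e[is.na(e)] <- tr[is.na(e)]
  if (anyNA(e)) {
    miss <- which(is.na(e), arr.ind = TRUE)[1, ]
    abort(paste0("pair potential missing for pair (", AA20[miss[1]], ", ",
                 AA20[miss[2]], ")"), class = "ptb_error_asset")
  }
  new_ptb_matrix(e, name = tools::file_path_sans_ext(basename(path)))
}

#' Path of the packaged synthetic contact potential
#' @return File path under the installed package's `extdata/`.
#' @export
default_matrix_path <- function() {
  system.file("extdata", "contact_potential_synthetic.tsv",
              package = "ptbscreen", mustWork = TRUE)
}

#' Write a pair-potential matrix as a lower-triangular table
#'
#' Inverse of [load_matrix()]: writes the header line of one-letter codes
#' followed by one lower-triangular row per residue.
#'
#' @param matrix A `ptb_matrix` (or symmetric 20x20 named matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  m <- matrix[AA20, AA20]
  lines <- c(paste(AA20, collapse = " "))
  for (i in seq_along(AA20)) {
    lines <- c(lines, paste(c(AA20[i], format(m[i, seq_len(i)], trim = TRUE)),
                            collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

## Strict lookup used by the scoring code: errors on non-standard residues
## so that an unmimicked pY can never silently score as zero.
pair_energy <- function(matrix, aa_pep, aa_dom) {
  bad <- !is_standard_aa(aa_pep) | !is_standard_aa(aa_dom)
  if (any(bad)) {
    abort(paste0("non-standard residue reached scoring: ",
                 paste(unique(c(aa_pep[bad], aa_dom[bad])), collapse = ", "),
                 " (apply the phosphomimic first)"),
          class = "ptb_error_contract")
  }
  matrix[cbind(aa_pep, aa_dom)]
}

#' @export
print.ptb_matrix <- function(x, ...) {
  cat("<ptb_matrix> ", attr(x, "name"), ": 20x20 symmetric contact potential\n",
      sep = "")
  cat("  range [", min(x), ", ", max(x), "]\n", sep = "")
  invisible(x)
}
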