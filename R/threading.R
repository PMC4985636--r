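#' Locate the NXXY / NPXY recognition motif in a peptide
#'
#' Scans for the four-residue anchor N-x-x-Y, where the tyrosine may be
#' phosphorylated (lowercase `"y"` token). When several occurrences exist,
#' an occurrence with a phosphorylated tyrosine is preferred; ties are
#' broken by the leftmost occurrence.
#'
#' @param seq Peptide sequence (one-letter codes, `"y"` = pY allowed).
#' @return A `ptb_motif`: list with `start` and `y_index` (1-based indices
#'   of the motif N and Y; `y_index = start + 3`), `motif_kind` (one of
#'   `"NXXY"`, `"NPXY"`, `"NXXpY"`, `"NPXpY"`) and `motif` (the 4-mer).
#' @export
find_motif <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  ch <- split1(seq)
  if (length(ch) < 4) {
    abort("sequence shorter than the 4-residue motif",
          class = "ptb_error_motif")
  }
  starts <- which(ch == "N")
  starts <- starts[starts + 3 <= length(ch) & ch[starts + 3] %in% c("Y", "y")]
  if (length(starts) == 0) {
    abort(paste0("no NXXY motif in '", seq, "'"), class = "ptb_error_motif")
  }
  phospho <- ch[starts + 3] == "y"
  start <- if (any(phospho)) starts[phospho][1] else starts[1]
  y_index <- start + 3L
  kind <- paste0("N", if (ch[start + 1] == "P") "P" else "X", "X",
                 if (ch[y_index] == "y") "pY" else "Y")
  structure(list(start = start, y_index = y_index, motif_kind = kind,
                 motif = substr(seq, start, y_index)),
            class = "ptb_motif")
}

#' Phosphotyrosine-to-glutamate mimic
#'
#' Replaces tyrosines with glutamate to mimic phosphorylation at the
#' residue level. The default mode `"all_tyr"` mutates every tyrosine
#' (phosphorylated `"y"` or not); `"motif_only"` mutates only the motif
#' tyrosine located by [find_motif()]. Both modes are idempotent.
#'
#' @param seq Character vector of peptide sequences.
#' @param mode `"all_tyr"` (default) or `"motif_only"`.
#' @return Character vector of mimicked sequences.
#' @export
apply_phosphomimic <- function(seq, mode = c("all_tyr", "motif_only")) {
  mode <- match.arg(mode)
  if (mode == "all_tyr") {
    return(gsub("[Yy]", "E", seq))
  }
  vapply(seq, function(s) {
    anchor <- find_motif(s)
    substr(s, anchor$y_index, anchor$y_index) <- "E"
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Thread a candidate peptide onto the template frame
#'
#' Aligns a candidate sequence to the template peptide by superposing their
#' motif tyrosines (template frame: Y = 0) and extending residue-by-residue
#' in both directions until either sequence ends — no gaps, overhangs
#' dropped. The phosphomimic is applied to the mapped residues, so the
#' result is directly scoreable. This is the residue-level analogue of
#' rebuilding side chains on a fixed template backbone.
#'
#' @param candidate Candidate peptide sequence (may contain `"y"`).
#' @param template_y_position 1-based index of the motif Y in the template
#'   peptide.
#' @param template_length Template peptide length (residues).
#' @param anchor Optional precomputed `ptb_motif` for the candidate;
#'   default locates it with [find_motif()].
#' @param mimic Phosphomimic mode passed to [apply_phosphomimic()], or
#'   `"none"`.
#' @param candidate_id Label carried into score tables.
#' @return A `ptb_threaded`: list with `candidate_id`, `sequence` (input),
#'   `mapping` (tibble: position, aa — post-mimic) and `unmapped`
#'   (template-frame positions with no candidate residue).
#' @export
thread_peptide <- function(candidate, template_y_position, template_length,
                           anchor = NULL, mimic = "all_tyr",
                           candidate_id = "peptide") {
  anchor <- anchor %||% find_motif(candidate)
  seq2 <- if (identical(mimic, "none")) candidate else {
    apply_phosphomimic(candidate, mimic)
  }
  ch <- split1(seq2)
  cand_y <- anchor$y_index
  template_positions <- seq_len(template_length) - template_y_position
  cand_index <- template_positions + cand_y
  ok <- cand_index >= 1 & cand_index <= length(ch)
  mapping <- tibble(position = template_positions[ok],
                    aa = ch[cand_index[ok]])
  structure(
    list(candidate_id = candidate_id, sequence = candidate,
         mapping = mapping, unmapped = template_positions[!ok]),
    class = "ptb_threaded"
  )
}

#' @export
print.ptb_threaded <- function(x, ...) {
  cat("<ptb_threaded> ", x$candidate_id, ": ", x$sequence, " -> positions ",
      min(x$mapping$position), "..", max(x$mapping$position),
      if (length(x$unmapped)) paste0(" (", length(x$unmapped), " unmapped)"),
      "\n", sep = "")
  invisible(x)
}

#' Score a panel of candidate peptides against a pocket map
#'
#' For each candidate: locate the motif, apply the phosphomimic, thread
#' onto the template frame of `pockets`, and sum the pair-potential over
#' all pocket contacts. Peptides without an NXXY motif are excluded from
#' the score table and reported separately.
#'
#' @param panel Tibble with columns `id` and `sequence` (a bare character
#'   vector of sequences is also accepted), optionally `label` and/or `kd`
#'   columns which are carried through.
#' @param pockets A `ptb_pockets` from [build_pockets()].
#' @param matrix A `ptb_matrix`.
#' @param mimic Phosphomimic mode (default `"all_tyr"`).
#' @return Tibble (input order) with columns of `panel` plus `score` and
#'   `n_terms`; attribute `"excluded"` holds a tibble (id, sequence,
#'   reason) of motif-less peptides.
#' @export
score_panel <- function(panel, pockets, matrix, mimic = "all_tyr") {
  if (is.character(panel)) {
    panel <- tibble(id = paste0("pep", seq_along(panel)), sequence = panel)
  }
  stopifnot(is.data.frame(panel), all(c("id", "sequence") %in% names(panel)),
            inherits(pockets, "ptb_pockets"))
  tmpl_len <- nrow(pockets$positions)
  tmpl_y <- which(pockets$positions$position == 0)

  rows <- pmap(list(panel$id, panel$sequence), function(id, sq) {
    anchor <- tryCatch(find_motif(sq), ptb_error_motif = function(e) NULL)
    if (is.null(anchor)) {
      return(list(ok = FALSE, id = id, sequence = sq,
                  reason = "no NXXY motif"))
    }
    th <- thread_peptide(sq, tmpl_y, tmpl_len, anchor = anchor,
                         mimic = mimic, candidate_id = id)
    sc <- score_peptide(pockets, th, matrix)
    list(ok = TRUE, id = id, score = sc$total,
         n_terms = nrow(sc$per_contact))
  })
  ok <- map_lgl(rows, "ok")
  scored <- tibble(id = map_chr(rows[ok], "id"),
                   score = map_dbl(rows[ok], "score"),
                   n_terms = vapply(rows[ok], function(r) r$n_terms,
                                    integer(1)))
  out <- panel |>
    inner_join(scored, by = "id")
  excluded <- tibble(
    id = map_chr(rows[!ok], "id"),
    sequence = map_chr(rows[!ok], "sequence"),
    reason = map_chr(rows[!ok], "reason")
  )
  attr(out, "excluded") <- excluded
  out
}
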