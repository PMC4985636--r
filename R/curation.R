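#' Percent identity between two sequences by global alignment
#'
#' Needleman-Wunsch global alignment (Biostrings) under a simple scoring
#' scheme (default match +1, mismatch 0, gap open/extend -1), with identity
#' defined as matched columns / total alignment columns x 100.
#'
#' @param a,b Amino-acid sequences (non-empty strings).
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (positive numbers, subtracted).
#' @return Percent identity in [0, 100].
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0,
                              gap_open = 1, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("sequences must be non-empty", class = "ptb_error_contract")
  }
  letters <- sort(unique(c(split1(toupper(a)), split1(toupper(b)))))
  sub <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub) <- match
  al <- Biostrings::pairwiseAlignment(
    toupper(a), toupper(b), type = "global", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- split1(as.character(Biostrings::alignedPattern(al)))
  sa <- split1(as.character(Biostrings::alignedSubject(al)))
  100 * sum(pa == sa & pa != "-") / length(pa)
}

#' All-against-all identity matrix
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams pairwise_identity
#' @return Symmetric numeric matrix of percent identities (diagonal 100),
#'   dimnames = sequence ids.
#' @export
identity_matrix <- function(seqs, match = 1, mismatch = 0, gap_open = 1,
                            gap_extend = 1) {
  stopifnot(length(seqs) >= 1)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(
          seqs[[i]], seqs[[j]], match = match, mismatch = mismatch,
          gap_open = gap_open, gap_extend = gap_extend)
      }
    }
  }
  m
}

#' Redundancy clustering at an identity threshold
#'
#' Single-linkage clustering of sequences: any two sequences with pairwise
#' identity at or above the threshold end up in the same cluster
#' (transitively). One representative per cluster is chosen — by default
#' deterministically (longest sequence, ties by lexicographic id); set
#' `representative = "random"` with a `seed` to reproduce a randomized
#' pick.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Percent identity threshold (default 90).
#' @param representative `"longest"` (default) or `"random"`.
#' @param seed Integer seed used when `representative = "random"`.
#' @inheritParams pairwise_identity
#' @return Tibble: id, sequence, cluster, is_representative.
#' @export
greedy_cluster <- function(seqs, threshold = 90,
                           representative = c("longest", "random"),
                           seed = NULL, match = 1, mismatch = 0,
                           gap_open = 1, gap_extend = 1) {
  representative <- match.arg(representative)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  names(seqs) <- ids
  if (length(seqs) == 1) {
    cl <- setNames(1L, ids)
  } else {
    m <- identity_matrix(seqs, match = match, mismatch = mismatch,
                         gap_open = gap_open, gap_extend = gap_extend)
    ## single linkage: components of the "identity >= threshold" graph are
    ## exactly the cutree groups at distance 100 - threshold
    tree <- hclust(as.dist(100 - m), method = "single")
    cl <- cutree(tree, h = 100 - threshold)
  }
  out <- tibble(id = ids, sequence = unname(seqs), cluster = unname(cl[ids]))
  reps <- out |>
    group_by(.data$cluster) |>
    summarise(rep_id = if (representative == "longest") {
      .data$id[order(-nchar(.data$sequence), .data$id)][1]
    } else {
      if (!is.null(seed)) set.seed(seed + .data$cluster[1])
      sample(.data$id, 1)
    }, .groups = "drop")
  out |>
    left_join(reps, by = "cluster") |>
    mutate(is_representative = .data$id == .data$rep_id) |>
    select(-"rep_id")
}

#' Read sequences from a FASTA file
#'
#' Case-preserving FASTA reader (so the lowercase pY token survives).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          forceDNAtolower = FALSE)
  setNames(unlist(lapply(s, as.character)), names(s))
}
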