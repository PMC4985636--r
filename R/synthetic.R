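#' Generate a toy two-chain complex with an exactly known contact map
#'
#' Builds PDB-format text for a synthetic domain (chain A) + peptide
#' (chain B) complex in which every residue carries a minimal five-atom set
#' (N, CA, C, O, CB) and the inter-chain contact structure is known by
#' construction: each designed (peptide, domain, distance) triple is
#' realized by placing the domain residue so the minimum inter-atomic
#' distance between the two residues equals the target to within 0.01
#' angstrom (solved numerically), while every non-designed residue pair is
#' kept farther than `cutoff + 1`. The geometry is verified before
#' returning; an unsatisfiable request errors. Fixtures are geometric
#' stand-ins only — no attempt is made at realistic protein folds.
#'
#' @param n_domain_residues,n_peptide_residues Residue counts
#'   (peptide >= 4).
#' @param contacts Data frame of designed contacts with columns `pep`
#'   (peptide residue index), `dom` (domain residue index), `distance`
#'   (target minimum distance, angstroms, in [2, 50]; at most 4 designed
#'   partners per peptide residue). May be empty/NULL.
#' @param peptide_seq,domain_seq Optional one-letter sequences (peptide may
#'   contain `"y"`); defaults: poly-alanine peptide, seeded random domain
#'   sequence.
#' @param seed Integer seed; jitters the residue layout and draws the
#'   domain sequence. Same seed, same arguments: byte-identical PDB text.
#' @param cutoff Contact cutoff the ground truth is expressed at
#'   (default 4.5).
#' @param path Optional file path; when given the PDB text is written there.
#' @return List with `pdb_text` (character vector of lines), `contacts`
#'   (ground-truth tibble: pep_resno, dom_resno, distance — designed pairs
#'   strictly below `cutoff`), and `path` (or NULL).
#' @export
make_complex <- function(n_domain_residues, n_peptide_residues,
                         contacts = NULL, peptide_seq = NULL,
                         domain_seq = NULL, seed = 1, cutoff = 4.5,
                         path = NULL) {
  if (n_peptide_residues < 4) {
    abort("peptide must have at least 4 residues",
          class = "ptb_error_contract")
  }
  contacts <- if (is.null(contacts)) {
    tibble(pep = integer(), dom = integer(), distance = double())
  } else {
    as_tibble(contacts)
  }
  stopifnot(all(c("pep", "dom", "distance") %in% names(contacts)))
  if (nrow(contacts) > 0) {
    if (any(contacts$pep < 1 | contacts$pep > n_peptide_residues) ||
        any(contacts$dom < 1 | contacts$dom > n_domain_residues)) {
      abort("designed contact indices out of range",
            class = "ptb_error_contract")
    }
    if (any(contacts$distance < 2 | contacts$distance > 50)) {
      abort("target distances must lie in [2, 50] angstroms",
            class = "ptb_error_generate")
    }
    if (any(duplicated(contacts$dom))) {
      abort("a domain residue may appear in only one designed contact",
            class = "ptb_error_generate")
    }
    if (any(table(contacts$pep) > 4)) {
      abort("infeasible geometry: more than 4 designed partners for one peptide residue",
            class = "ptb_error_generate")
    }
  }
  peptide_seq <- peptide_seq %||% strrep("A", n_peptide_residues)
  pep_aa <- split1(peptide_seq)
  if (length(pep_aa) != n_peptide_residues) {
    abort("peptide_seq length mismatch", class = "ptb_error_contract")
  }
  set.seed(seed)
  dom_aa <- if (is.null(domain_seq)) {
    sample(AA20, n_domain_residues, replace = TRUE)
  } else {
    split1(domain_seq)
  }
  if (length(dom_aa) != n_domain_residues) {
    abort("domain_seq length mismatch", class = "ptb_error_contract")
  }

  off <- residue_atom_offsets()
  ## peptide residues strung along y; spacing 20 A >> cutoff so only the
  ## designed placements can create contacts
  pep_centers <- cbind(0, (seq_len(n_peptide_residues) - 1) * 20, 0) +
    matrix(runif(3 * n_peptide_residues, -1, 1), ncol = 3)
  ## far-away default grid for domain residues
  j <- seq_len(n_domain_residues) - 1
  dom_centers <- cbind(200 + 20 * (j %% 10), 20 * (j %/% 10), 0) +
    matrix(runif(3 * n_domain_residues, -1, 1), ncol = 3)

  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1), c(0, 0, -1))
  if (nrow(contacts) > 0) {
    contacts <- arrange(contacts, .data$pep, .data$dom)
    slot <- stats::ave(contacts$pep, contacts$pep, FUN = seq_along)
    for (k in seq_len(nrow(contacts))) {
      u <- dirs[slot[k], ]
      s <- solve_center_separation(off, u, contacts$distance[k])
      dom_centers[contacts$dom[k], ] <- pep_centers[contacts$pep[k], ] + s * u
    }
  }

  verify_complex_geometry(pep_centers, dom_centers, off, contacts, cutoff)

  lines <- render_pdb(pep_centers, dom_centers, pep_aa, dom_aa, off, seed)
  if (!is.null(path)) writeLines(lines, path)
  truth <- contacts |>
    filter(.data$distance < cutoff) |>
    transmute(pep_resno = as.integer(.data$pep),
              dom_resno = as.integer(.data$dom),
              distance = .data$distance) |>
    arrange(.data$pep_resno, .data$dom_resno)
  list(pdb_text = lines, contacts = truth, path = path)
}

## Fixed local atom geometry shared by every synthetic residue.
residue_atom_offsets <- function() {
  m <- rbind(
    N  = c(-0.75, 0.45, 0.00),
    CA = c(0.00, 0.00, 0.00),
    C  = c(0.75, 0.45, 0.00),
    O  = c(1.00, 1.10, 0.60),
    CB = c(-0.20, -0.90, 0.80)
  )
  m
}

## Solve for the center separation s along direction u such that the
## minimum atom-pair distance between two identically oriented residues
## equals d. Monotone in s once s exceeds the projection spread of the
## atom offsets on u, so uniroot is safe on [lo, 60].
solve_center_separation <- function(off, u, d) {
  mind <- function(s) {
    delta <- matrix(rep(off, each = nrow(off)), ncol = 3)  # b replicated
    a <- off[rep(seq_len(nrow(off)), times = nrow(off)), ]
    min(sqrt(rowSums((matrix(s * u, nrow(a), 3, byrow = TRUE) + delta - a)^2)))
  }
  proj <- off %*% u
  lo <- diff(range(proj)) + 0.01
  if (mind(lo) >= d) {
    abort(paste0("infeasible geometry: target distance ", d,
                 " too small for the residue atom clusters"),
          class = "ptb_error_generate")
  }
  uniroot(function(s) mind(s) - d, c(lo, 60), tol = 1e-10)$root
}

verify_complex_geometry <- function(pep_centers, dom_centers, off, contacts,
                                    cutoff) {
  designed <- paste(contacts$pep, contacts$dom)
  for (i in seq_len(nrow(pep_centers))) {
    pa <- sweep(off, 2, pep_centers[i, ], "+")
    for (j in seq_len(nrow(dom_centers))) {
      da <- sweep(off, 2, dom_centers[j, ], "+")
      md <- min(cross_dist(pa, da))
      key <- paste(i, j)
      if (key %in% designed) {
        tgt <- contacts$distance[designed == key]
        if (abs(md - tgt) > 0.01) {
          abort(paste0("generation error: achieved distance ", round(md, 3),
                       " != target ", tgt, " for pair (", key, ")"),
                class = "ptb_error_generate")
        }
      } else if (md <= cutoff + 1) {
        abort(paste0("generation error: undesigned pair (", key,
                     ") at distance ", round(md, 2)),
              class = "ptb_error_generate")
      }
    }
  }
  invisible(TRUE)
}

render_pdb <- function(pep_centers, dom_centers, pep_aa, dom_aa, off, seed) {
  res3 <- function(aa) {
    ifelse(aa == "y", "PTR", unname(AA1TO3[aa]))
  }
  atom_lines <- function(centers, aa, chain, serial0) {
    out <- character(0)
    serial <- serial0
    for (i in seq_len(nrow(centers))) {
      for (k in seq_len(nrow(off))) {
        xyz <- centers[i, ] + off[k, ]
        nm <- rownames(off)[k]
        out <- c(out, sprintf(
          "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", nm), res3(aa[i]), chain, i,
          xyz[1], xyz[2], xyz[3], 1, 0, substr(nm, 1, 1)))
        serial <- serial + 1
      }
    }
    list(lines = out, serial = serial)
  }
  a <- atom_lines(dom_centers, dom_aa, "A", 1)
  b <- atom_lines(pep_centers, pep_aa, "B", a$serial)
  c(sprintf("REMARK   1 SYNTHETIC COMPLEX (ptbscreen make_complex, seed %d)",
            as.integer(seed)),
    a$lines, "TER", b$lines, "TER", "END")
}

#' Generate a labeled peptide panel with planted binding signal
#'
#' Emulates a binder / non-binder peptide panel over the pocket map of a
#' template complex. Every generated sequence carries the recognition
#' motif in the template register (Asn at position -3, phosphotyrosine
#' token `"y"` at position 0). Non-binder sequences draw the remaining
#' positions uniformly from the 20 standard residues; binder sequences are
#' drawn at pocket-contacting positions from a Boltzmann-like bias toward
#' low pocket energy, with the inverse temperature solved numerically so
#' that the *expected* binder / non-binder score separation equals
#' `effect_size` (in matrix energy units). `noise_sd` blurs the planted
#' signal by perturbing the per-position energies used for sampling each
#' binder. Optionally, synthetic dissociation constants are attached,
#' log-linearly coupled to the peptide's deterministic pipeline score with
#' Gaussian noise.
#'
#' @param pockets A `ptb_pockets` with at least one occupied pocket.
#' @param matrix A `ptb_matrix`.
#' @param n_binders,n_nonbinders Panel sizes (defaults 69 / 54, the size of
#'   the published ShcA peptide-array panel split).
#' @param effect_size Target mean score separation, matrix units
#'   (default 3; 0 plants no signal).
#' @param noise_sd Per-binder Gaussian sd on sampling energies
#'   (default 0.25).
#' @param kd_coupling `NULL`, or list `(slope, intercept, sd)`:
#'   `log Kd = slope * score + intercept + N(0, sd)`, Kd in molar. Default
#'   slope 1, intercept -12, sd 0.5 (micromolar-range affinities).
#' @param mimic Phosphomimic mode used when computing the coupling score.
#' @param seed Integer seed; one stream drives all sampling.
#' @return Tibble: id, sequence, label, and `kd` when coupled. Attribute
#'   `"spec"` records the generator parameters.
#' @export
make_panel <- function(pockets, matrix, n_binders = 69, n_nonbinders = 54,
                       effect_size = 3, noise_sd = 0.25,
                       kd_coupling = list(slope = 1, intercept = -12,
                                          sd = 0.5),
                       mimic = "all_tyr", seed = 1) {
  stopifnot(inherits(pockets, "ptb_pockets"), n_binders >= 0,
            n_nonbinders >= 0, noise_sd >= 0, effect_size >= 0)
  if (nrow(pockets$contacts) == 0) {
    abort("pocket map has no occupied pockets", class = "ptb_error_contract")
  }
  positions <- pockets$positions$position
  if (!all(c(-3, 0) %in% positions)) {
    abort("template frame must cover positions -3..0 (the motif)",
          class = "ptb_error_contract")
  }
  fixed <- c(`-3` = "N", `0` = "y")
  variable <- setdiff(positions, c(-3, 0))

  ## summed pocket energy of each residue choice, per variable position
  m <- unclass(matrix)
  pos_energy <- lapply(variable, function(p) {
    dom <- pockets$contacts$dom_aa[pockets$contacts$position == p]
    if (length(dom) == 0) {
      setNames(rep(0, 20), AA20)
    } else {
      colSums(m[dom, AA20, drop = FALSE])
    }
  })
  names(pos_energy) <- as.character(variable)

  beta <- solve_bias_beta(pos_energy, effect_size)

  set.seed(seed)
  draw_seq <- function(biased) {
    aa <- character(length(positions))
    names(aa) <- as.character(positions)
    aa[names(fixed)] <- fixed
    for (p in as.character(variable)) {
      e <- pos_energy[[p]]
      if (biased && beta > 0 && any(e != 0)) {
        if (noise_sd > 0) e <- e + rnorm(20, 0, noise_sd)
        w <- exp(-beta * (e - min(e)))
        aa[p] <- sample(AA20, 1, prob = w / sum(w))
      } else {
        aa[p] <- sample(AA20, 1)
      }
    }
    paste(aa[as.character(positions)], collapse = "")
  }
  panel <- tibble(
    id = c(sprintf("binder_%03d", seq_len(n_binders)),
           sprintf("nonbinder_%03d", seq_len(n_nonbinders))),
    sequence = c(vapply(seq_len(n_binders), function(i) draw_seq(TRUE),
                        character(1)),
                 vapply(seq_len(n_nonbinders), function(i) draw_seq(FALSE),
                        character(1))),
    label = rep(c("binder", "nonbinder"), c(n_binders, n_nonbinders))
  )
  if (!is.null(kd_coupling)) {
    scored <- score_panel(panel, pockets, matrix, mimic = mimic)
    ln_kd <- kd_coupling$slope * scored$score + kd_coupling$intercept +
      rnorm(nrow(scored), 0, kd_coupling$sd)
    panel$kd <- exp(ln_kd)[match(panel$id, scored$id)]
  }
  attr(panel, "spec") <- list(n_binders = n_binders,
                              n_nonbinders = n_nonbinders,
                              effect_size = effect_size, noise_sd = noise_sd,
                              kd_coupling = kd_coupling, seed = seed,
                              beta = beta)
  panel
}

## Expected score separation between uniform and Boltzmann-biased sampling,
## summed over positions; solve for the inverse temperature achieving the
## requested separation.
solve_bias_beta <- function(pos_energy, effect_size) {
  if (effect_size == 0) {
    return(0)
  }
  sep <- function(beta) {
    sum(vapply(pos_energy, function(e) {
      if (all(e == 0)) return(0)
      w <- exp(-beta * (e - min(e)))
      mean(e) - sum(w * e) / sum(w)
    }, double(1)))
  }
  max_sep <- sep(200)
  if (effect_size >= max_sep) {
    abort(paste0("effect_size ", effect_size,
                 " exceeds the achievable separation (",
                 round(max_sep, 2), ") for this pocket map"),
          class = "ptb_error_generate")
  }
  uniroot(function(b) sep(b) - effect_size, c(0, 200), tol = 1e-9)$root
}

#' Write a peptide panel as TSV
#' @param panel Tibble with at least id and sequence columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  readr::write_tsv(panel, path)
  invisible(path)
}
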