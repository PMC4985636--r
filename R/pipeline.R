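#' Run the full screening pipeline from one configuration
#'
#' Orchestrates template parsing, contact/pocket extraction, motif-anchored
#' threading with phosphomimic, pair-potential scoring of a candidate
#' panel, and the ROC/correlation benchmark, writing all results plus a
#' provenance record into a run directory. Deterministic given the
#' configuration and seed.
#'
#' Configuration fields (list or JSON file): `template_pdb`,
#' `domain_chains`, `peptide_chain`, `panel` (TSV/FASTA path or data
#' frame), `out_dir`; optional `model` (1), `contact_cutoff` (4.5),
#' `y_position` (auto from motif), `phosphomimic` ("all_tyr"),
#' `matrix_path` (packaged synthetic potential), `labels` / `affinities`
#' (paths or data frames; a `label` / `kd` column in the panel is also
#' used), `temperature` (300), `seed` (1).
#'
#' @param config A named list or a path to a JSON configuration file.
#' @param quiet Suppress progress messages (they always go to the run log).
#' @return A `ptb_run`: list with `dir`, `scores`, `report`, `config`.
#' @export
run_screen <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "ptb_error_io")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(model = 1, contact_cutoff = 4.5, y_position = NULL,
                   phosphomimic = "all_tyr", matrix_path = NULL,
                   labels = NULL, affinities = NULL, temperature = 300,
                   seed = 1)
  config <- utils::modifyList(defaults, config)
  required <- c("template_pdb", "domain_chains", "peptide_chain", "panel",
                "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0) {
    abort(paste0("config is missing field(s): ", paste(miss, collapse = ", ")),
          class = "ptb_error_config")
  }
  matrix_path <- config$matrix_path %||% default_matrix_path()
  for (p in c(config$template_pdb, matrix_path,
              if (is.character(config$panel)) config$panel,
              if (is.character(config$labels)) config$labels,
              if (is.character(config$affinities)) config$affinities)) {
    if (!file.exists(p)) {
      abort(paste0("input file not found: ", p), class = "ptb_error_config")
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage: ", name)
    tryCatch(expr, error = function(e) {
      log_line("FAILED at stage '", name, "': ", conditionMessage(e))
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = "ptb_error_stage", parent = e)
    })
  }
  set.seed(config$seed)

  pot <- stage("load_matrix", load_matrix(matrix_path))
  templ <- stage("parse_template",
                 parse_pdb(config$template_pdb, config$domain_chains,
                           config$peptide_chain, model = config$model))
  contacts <- stage("contacts",
                    compute_contacts(templ, cutoff = config$contact_cutoff))
  pockets <- stage("pockets", build_pockets(contacts, config$y_position))
  panel <- stage("read_panel", if (is.data.frame(config$panel)) {
    as_tibble(config$panel)
  } else {
    read_panel(config$panel)
  })
  scores <- stage("score_panel",
                  score_panel(panel, pockets, pot,
                              mimic = config$phosphomimic))
  log_line(nrow(scores), " peptides scored, ",
           nrow(attr(scores, "excluded")), " excluded (no motif)")

  labels <- resolve_table(config$labels, panel, "label")
  affinities <- resolve_table(config$affinities, panel, "kd")
  report <- NULL
  if (!is.null(labels) || !is.null(affinities)) {
    report <- stage("benchmark",
                    benchmark_report(scores, labels = labels,
                                     affinities = affinities,
                                     temperature = config$temperature))
  }

  stage("write_outputs", {
    write_contacts_tsv(contacts, file.path(config$out_dir, "contacts.tsv"))
    write_contacts_tsv(pockets, file.path(config$out_dir, "pockets.tsv"))
    readr::write_tsv(scores, file.path(config$out_dir, "scores.tsv"))
    readr::write_tsv(attr(scores, "excluded"),
                     file.path(config$out_dir, "excluded.tsv"))
    if (!is.null(report)) write_benchmark_report(report, config$out_dir)
    provenance <- list(
      package = "ptbscreen",
      version = as.character(utils::packageVersion("ptbscreen")),
      seed = config$seed,
      matrix_md5 = unname(tools::md5sum(matrix_path)),
      template_md5 = unname(tools::md5sum(config$template_pdb)),
      config = config[!vapply(config, is.data.frame, logical(1))]
    )
    jsonlite::write_json(provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })
  log_line("run complete: ", config$out_dir)
  structure(list(dir = config$out_dir, scores = scores, report = report,
                 config = config),
            class = "ptb_run")
}

## labels/affinities may come as a path, a data frame, or implicitly as a
## column of the panel
resolve_table <- function(x, panel, column) {
  if (is.null(x)) {
    if (column %in% names(panel)) {
      tab <- panel[, c("id", column)]
      return(tab[!is.na(tab[[column]]), ])
    }
    return(NULL)
  }
  if (is.character(x))

    x <- readr::read_tsv(x, show_col_types = FALSE)
  as_tibble(x)
}

#' Read a candidate peptide panel from TSV or FASTA
#'
#' TSV files need `id` (or `peptide_id`) and `sequence` columns; `label`
#' and `kd` columns are carried through. FASTA input (detected by a
#' leading `>`) preserves case, so phosphotyrosines encoded as lowercase
#' `"y"` survive.
#'
#' @param path Input file path.
#' @return Tibble with `id`, `sequence` and any extra columns.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path), class = "ptb_error_io")
  }
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    seqs <- read_fasta_seqs(path)
    return(tibble(id = names(seqs), sequence = unname(seqs)))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if ("peptide_id" %in% names(tab) && !"id" %in% names(tab)) {
    tab <- rename(tab, id = "peptide_id")
  }
  if (!all(c("id", "sequence") %in% names(tab))) {
    abort("panel TSV must have 'id' and 'sequence' columns",
          class = "ptb_error_io")
  }
  tab
}

#' @export
print.ptb_run <- function(x, ...) {
  cat("<ptb_run> ", x$dir, ": ", nrow(x$scores), " peptides scored\n",
      sep = "")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
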