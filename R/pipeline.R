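## End-to-end orchestration: one configuration object, deterministic
## per-stage seeding, per-stage outputs and a machine-readable run report.

.PIPELINE_STAGES <- c("simulate_screen", "screen_score", "simulate_circrnas",
                      "orf_survey", "junction_db", "simulate_psms",
                      "psm_filter")

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Stage parameter
#' blocks default to each stage's documented defaults; unknown keys are
#' rejected by name.
#'
#' @param stages Stages to run, a subset of the known stage names; stages
#'   run in fixed dependency order regardless of the order given.
#' @param seed Master seed; per-stage seeds are derived deterministically
#'   from it and the stage's position.
#' @param screen List overriding [screen_sim_config()] arguments.
#' @param score List with `z_hi`, `z_lo`.
#' @param circs List overriding [simulate_circrnas()] arguments
#'   (`n`, `props`, `p_overlap`, `p_homolog`).
#' @param orfs List with `min_aa`, `min_overlap_aa`, `max_mismatch`.
#' @param pepdb List with `min_len`, `min_flank`, `max_missed`.
#' @param psms List overriding [simulate_psms()] arguments (`n_true`,
#'   `violators`) and [filter_psms()] thresholds (`max_q`, `max_mismatch`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stages = .PIPELINE_STAGES, seed = 1L,
                            screen = list(), score = list(),
                            circs = list(), orfs = list(),
                            pepdb = list(), psms = list()) {
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  check_keys <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s' block: %s", name,
                   paste(bad, collapse = ", ")), call. = FALSE)
    block
  }
  structure(list(
    stages = .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages],
    seed = as.integer(seed),
    screen = check_keys(screen, c("n_inserts", "planted_hexamers",
                                  "p_active", "p_background",
                                  "reads_per_fraction", "error_rate"),
                        "screen"),
    score = check_keys(score, c("z_hi", "z_lo"), "score"),
    circs = check_keys(circs, c("n", "props", "p_overlap", "p_homolog"),
                       "circs"),
    orfs = check_keys(orfs, c("min_aa", "min_overlap_aa", "max_mismatch"),
                      "orfs"),
    pepdb = check_keys(pepdb, c("min_len", "min_flank", "max_missed"),
                       "pepdb"),
    psms = check_keys(psms, c("n_true", "violators", "max_q",
                              "max_mismatch", "n_ref_proteins"), "psms")
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration (JSON)
#'
#' The configuration round-trips losslessly through its file form; unknown
#' keys fail validation by name.
#'
#' @param path JSON file.
#' @param config A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("stages", "seed", "screen", "score", "circs", "orfs", "pepdb",
             "psms")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown key(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

stage_seed <- function(config, stage) {
  (config$seed %% 1000000L) * 1009L +
    match(stage, .PIPELINE_STAGES) * 7919L
}

#' Run the pipeline
#'
#' Executes the selected stages in dependency order, writing per-stage
#' outputs under `out_dir` and a machine-readable `run_report.json`
#' (package version, parameters, per-stage record counts). Reruns with
#' identical configuration reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The run report, invisibly (list with `stages` data.frame).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  counts <- list()
  log_stage <- function(stage, n, output) {
    message(sprintf("[%s] %d records -> %s", stage, n, output))
    counts[[stage]] <<- data.frame(stage = stage, n_records = n,
                                   output = output,
                                   stringsAsFactors = FALSE)
  }
  for (stage in config$stages) {
    sd <- stage_seed(config, stage)
    if (stage == "simulate_screen") {
      cfg <- do.call(screen_sim_config, c(config$screen, list(seed = sd)))
      state$screen <- simulate_screen(cfg, out_dir = file.path(out_dir,
                                                               "screen"))
      log_stage(stage, sum(lengths(state$screen$reads)),
                file.path(out_dir, "screen"))
    } else if (stage == "screen_score") {
      if (is.null(state$screen))
        stop("screen_score requires simulate_screen output", call. = FALSE)
      ctx <- vector_context()
      green <- extract_inserts(c(state$screen$reads$medium,
                                 state$screen$reads$high), ctx, "green")
      dark <- extract_inserts(state$screen$reads$negative, ctx, "negative")
      sc <- do.call(score_enrichment,
                    c(list(count_hexamers(green, ctx),
                           count_hexamers(dark, ctx)), config$score))
      out <- file.path(out_dir, "hexamer_scores.tsv")
      write_score_table(sc, out)
      state$scores <- sc
      log_stage(stage, nrow(sc), out)
    } else if (stage == "simulate_circrnas") {
      sim <- do.call(simulate_circrnas,
                     c(config$circs, list(seed = sd,
                                          out_dir = file.path(out_dir,
                                                              "circs"))))
      state$circ_sim <- sim
      log_stage(stage, nrow(sim$circs), file.path(out_dir, "circs"))
    } else if (stage == "orf_survey") {
      if (is.null(state$circ_sim))
        stop("orf_survey requires simulate_circrnas output", call. = FALSE)
      sv <- do.call(survey_orfs,
                    c(list(state$circ_sim$circs,
                           host_proteins = state$circ_sim$host_proteins,
                           known_proteins = state$circ_sim$known_proteins),
                      config$orfs))
      out <- file.path(out_dir, "orf_survey.tsv")
      write.table(sv$per_circ, out, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      state$survey <- sv
      log_stage(stage, nrow(sv$per_circ), out)
    } else if (stage == "junction_db") {
      if (is.null(state$circ_sim))
        stop("junction_db requires simulate_circrnas output", call. = FALSE)
      db <- do.call(build_junction_db,
                    c(list(state$circ_sim$circs), config$pepdb))
      out <- file.path(out_dir, "junction_db.fa")
      write_junction_db(db, out)
      state$db <- db
      log_stage(stage, nrow(db), out)
    } else if (stage == "simulate_psms") {
      if (is.null(state$db))
        stop("simulate_psms requires junction_db output", call. = FALSE)
      nref <- config$psms$n_ref_proteins
      if (is.null(nref)) nref <- 20L
      state$reference <- simulate_reference_proteome(nref, seed = sd + 1L)
      sim_args <- config$psms[intersect(names(config$psms),
                                        c("n_true", "violators"))]
      state$psm_sim <- do.call(simulate_psms,
                               c(list(db = state$db,
                                      reference = state$reference,
                                      seed = sd,
                                      out_dir = file.path(out_dir, "psms")),
                                 sim_args))
      log_stage(stage, nrow(state$psm_sim$psms), file.path(out_dir, "psms"))
    } else if (stage == "psm_filter") {
      if (is.null(state$psm_sim))
        stop("psm_filter requires simulate_psms output", call. = FALSE)
      filt_args <- config$psms[intersect(names(config$psms),
                                         c("max_q", "max_mismatch"))]
      fr <- do.call(filter_psms, c(list(state$psm_sim$psms,
                                        state$reference), filt_args))
      out <- file.path(out_dir, "psms_filtered.tsv")
      write_psm_table(fr$psms, out)
      write.table(fr$report, file.path(out_dir, "filter_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      sm <- spectra_summaries(fr$psms)
      write.table(sm, file.path(out_dir, "spectra_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      state$filtered <- fr
      log_stage(stage, nrow(fr$psms), out)
    }
  }
  report <- list(
    package = "circtrans",
    version = as.character(utils::packageVersion("circtrans")),
    seed = config$seed,
    parameters = unclass(config),
    stages = do.call(rbind, unname(counts))
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
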