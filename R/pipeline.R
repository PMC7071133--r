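# Pipeline driver: chains cohort simulation, outcome summaries, the MDS
# screening, subgroup flags, the feedback analysis and the ANOVA layer into
# one reproducible run with a provenance stamp.

#' Default pipeline configuration
#'
#' @param seed root seed; every stage derives its randomness from it.
#' @param out_dir output directory (NULL = no files written).
#' @param stages subset of `c("simulate", "mds", "flags", "feedback",
#'   "anova")`.
#' @param n_participants cohort size.
#' @param meas_sd outcome measurement error (m).
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1, out_dir = NULL,
                           stages = c("simulate", "mds", "flags",
                                      "feedback", "anova"),
                           n_participants = 12, meas_sd = 0.003) {
  structure(list(seed = seed, out_dir = out_dir, stages = stages,
                 n_participants = n_participants, meas_sd = meas_sd,
                 package_version = as.character(utils::packageVersion("holosteps"))),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order: cohort simulation (trial-level
#' outcomes), feature vectors + distance matrix + MDS, subgroup flags,
#' feedback-series reports for the flagged participants, and the
#' repeated-measures ANOVA of the condition summaries. When `out_dir` is
#' set, every stage writes its tables as CSV/JSON next to a resolved copy
#' of the configuration (the provenance stamp).
#'
#' @param config a [default_config()] list.
#' @return a `run_report` list with the stage outputs and bookkeeping
#'   counts.
#' @export
run_pipeline <- function(config = default_config()) {
  report <- list(config = config, counts = list())
  out_dir <- config$out_dir
  emit <- function(name, obj, writer) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writer(obj, file.path(out_dir, name))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    report$provenance <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                              package_version = config$package_version)
  }
  if (!length(config$stages)) return(structure(report, class = "run_report"))

  design <- design_cohort(config$n_participants, seed = config$seed)
  outcomes <- NULL
  if ("simulate" %in% config$stages) {
    outcomes <- simulate_cohort_outcomes(design, meas_sd = config$meas_sd)
    report$counts$trials <- nrow(outcomes)
    emit("outcomes.csv", outcomes,
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    summaries <- summarize_trials(outcomes)
    report$summaries <- summaries
    emit("summaries.csv", summaries,
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }
  if (any(c("mds", "flags") %in% config$stages) && is.null(outcomes))
    stop("mds/flags stages need the simulate stage (or supplied outcomes)")

  if ("mds" %in% config$stages) {
    fv <- suppressWarnings(build_feature_vectors(outcomes))
    D <- distance_matrix(fv)
    emb <- mds_embed(D)
    report$counts$feature_vectors <- nrow(fv$values)
    report$counts$vector_length <- ncol(fv$values)
    report$counts$distance_matrix_dim <- dim(D)
    report$mds <- emb
    report$holo_real_distance <- holo_real_distance(D)
    emit("distance_matrix.csv", as.data.frame(as.matrix(D)),
         function(o, p) utils::write.csv(o, p))
    emit("embedding.csv", as.data.frame(emb$points),
         function(o, p) utils::write.csv(o, p))
  }
  if ("flags" %in% config$stages) {
    flags <- flag_subgroups(outcomes)
    report$flags <- flags
    emit("flags.json", flags,
         function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                             digits = NA))
  }
  if ("feedback" %in% config$stages) {
    flagged <- if (!is.null(report$flags))
      report$flags[report$flags$label != "similar", ] else
      data.frame(participant = design$participants$participant,
                 label = design$participants$mode)[
                   design$participants$mode != "similar", ]
    fb_rows <- lapply(seq_len(nrow(flagged)), function(i) {
      p <- flagged$participant[i]
      prof <- cohort_profile(design, p)
      sd2 <- child_seed(config$seed, 5000L + i)
      real <- simulate_exp2_outcomes(prof, obstacle_spec("real", 0.3, 0.02),
                                     seed = sd2, participant = p)
      holo <- simulate_exp2_outcomes(prof,
                                     obstacle_spec("holographic", 0.3, 0.02),
                                     seed = child_seed(sd2, 1L),
                                     participant = p)
      measure <- if (flagged$label[i] == "no_trail_raise")
        "trail_cross" else "lead_cross"
      feedback_report(real, holo, measure)
    })
    report$feedback <- do.call(rbind, fb_rows)
    emit("feedback_report.csv", report$feedback,
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }
  if ("anova" %in% config$stages) {
    if (is.null(report$summaries)) stop("anova stage needs summaries")
    sm <- report$summaries
    lead_step <- sm[sm$outcome == "lead_step" & !is.na(sm$median), ]
    report$anova <- rm_anova(lead_step, dv = "median",
                             within = c("obstacle_type", "height", "depth"))
    emit("anova_lead_step.csv", as.data.frame(report$anova),
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (length(x$counts)) utils::str(x$counts, give.attr = FALSE)
  if (!is.null(x$flags)) {
    cat("subgroup flags:\n")
    print(table(x$flags$label))
  }
  invisible(x)
}
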