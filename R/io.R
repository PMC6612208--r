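#' Read a hierarchy configuration file
#'
#' The config is YAML or JSON (chosen by file extension) with keys
#' \code{goal}, \code{criteria} (mapping criterion label to its list of
#' sub-criterion labels), \code{alternatives}, and optionally
#' \code{score_panels} (per alternative: \code{safety} five scores,
#' \code{legal} six scores, \code{investment}, \code{purchase_cost}).
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A list with a validated \code{hierarchy}
#'   (\code{decision_hierarchy}) and \code{score_panels} (named list of
#'   [score_panel()] or \code{NULL}).
#' @export
read_hierarchy_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be .yaml, .yml or .json, got .", ext, call. = FALSE))
  h <- build_hierarchy(cfg)
  panels <- NULL
  if (!is.null(cfg$score_panels)) {
    panels <- lapply(cfg$score_panels, function(p) {
      score_panel(as.numeric(p$safety), as.numeric(p$legal),
                  as.numeric(p$investment), as.numeric(p$purchase_cost))
    })
    extra <- setdiff(names(panels), h$alternatives)
    if (length(extra) > 0) {
      stop("score panel for unknown alternative(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  list(hierarchy = h, score_panels = panels)
}

#' Read per-respondent pairwise judgments from CSV
#'
#' Columns: \code{respondent_id}, \code{node}, \code{child_a},
#' \code{child_b}, \code{answer}.  Answers may be numeric ratios (either
#' \code{.} or \code{,} decimal mark), exact fractions like \code{"1/7"},
#' or Saaty / questionnaire labels (see [saaty_value()]); they are kept
#' as character and interpreted by [build_group_matrix()].
#'
#' @param path CSV path.
#' @return Data frame of judgments.
#' @export
read_judgments_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("respondent_id", "node", "child_a", "child_b", "answer")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("judgments CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Write judgments to CSV
#' @param judgments Data frame as produced by [generate_judgments()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_judgments_csv <- function(judgments, path) {
  utils::write.csv(judgments, path, row.names = FALSE)
  invisible(path)
}

#' Read Likert questionnaire answers from CSV
#'
#' Columns: \code{respondent_id}, \code{item_id}, \code{answer}
#' (agreement-category labels).
#'
#' @param path CSV path.
#' @return Data frame of raw answers.
#' @export
read_likert_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "item_id", "answer")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("Likert CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Write Likert answers to CSV
#' @param answers Data frame as produced by [generate_likert()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_likert_csv <- function(answers, path) {
  utils::write.csv(answers, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-timestep operational series from CSV
#' @param path CSV path; must contain the [timestep_columns()].
#' @return Data frame of timestep records.
#' @export
read_timesteps_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(timestep_columns(), names(d))
  if (length(miss) > 0) {
    stop("timesteps CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Write a timestep series to CSV
#' @param records Data frame as produced by [generate_timesteps()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_timesteps_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

# tag stage errors so pipeline failures name the failing stage
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full assessment pipeline
#'
#' Orchestrates every stage: per-node group aggregation of judgments,
#' eigenvector priorities with consistency screening, weight propagation,
#' optional indicator-based alternative scoring and priority synthesis
#' (when a timestep series and score panels are supplied), optional
#' Likert scoring, and — when both weights and satisfaction are
#' available — the importance-satisfaction gap analysis.
#'
#' @param hierarchy_config Path to a hierarchy config file, or the list
#'   returned by [read_hierarchy_config()].
#' @param judgments Path to a judgments CSV, or a judgments data frame.
#' @param likert Optional path to a Likert CSV, or a data frame.
#' @param timesteps Optional path to a timestep CSV, or a data frame
#'   (requires score panels in the config).
#' @param cr_threshold Consistency-ratio acceptability cutoff (default
#'   0.1).
#' @param rounding Round aggregated group judgments to the Saaty scale
#'   (default \code{TRUE}).
#' @param strict Reject (rather than warn about) matrices with CR above
#'   threshold.
#' @param gap_thresholds Optional cutoff list for
#'   [importance_satisfaction()].
#' @param out_dir Optional directory: writes \code{report.json},
#'   \code{weights.csv} and, when computed, \code{gap.csv}.
#' @return The assessment report: a list with elements \code{schema},
#'   \code{goal}, \code{nodes} (per node: matrix, consistency, local
#'   weights), \code{global_weights}, \code{needs}, and when available
#'   \code{alternatives}, \code{likert}, \code{satisfaction}, \code{gap},
#'   plus the \code{options} used.
#' @export
run_full_assessment <- function(hierarchy_config, judgments, likert = NULL,
                                timesteps = NULL, cr_threshold = 0.1,
                                rounding = TRUE, strict = FALSE,
                                gap_thresholds = NULL, out_dir = NULL) {
  cfg <- .stage("config", {
    if (is.character(hierarchy_config)) {
      read_hierarchy_config(hierarchy_config)
    } else hierarchy_config
  })
  h <- cfg$hierarchy
  jd <- .stage("judgments", {
    if (is.character(judgments)) read_judgments_csv(judgments) else judgments
  })
  nodes <- c("goal", names(h$criteria))
  node_reports <- list()
  for (nd in nodes) {
    children <- .node_children(h, nd)
    if (length(children) < 2) {
      h <- set_local_weights(h, nd, 1)
      next
    }
    M <- .stage(paste0("aggregate:", nd),
                build_group_matrix(jd, node = nd, labels = children,
                                   rounding = rounding))
    h <- .stage(paste0("priorities:", nd),
                assess_node(h, nd, M, threshold = cr_threshold,
                            strict = strict))
    node_reports[[nd]] <- list(
      matrix = unclass(M),
      consistency = unclass(h$consistency[[nd]]),
      local_weights = stats::setNames(h$local[[nd]], children))
  }
  h <- .stage("propagate", propagate_weights(h))
  report <- list(
    schema = "ahpgap-report/1",
    goal = h$goal,
    nodes = node_reports,
    global_weights = h$global,
    needs = hierarchy_of_needs(h$global),
    options = list(cr_threshold = cr_threshold, rounding = rounding,
                   strict = strict)
  )
  if (!is.null(timesteps)) {
    ts <- .stage("timesteps", {
      if (is.character(timesteps)) read_timesteps_csv(timesteps) else timesteps
    })
    if (is.null(cfg$score_panels)) {
      stop("[stage indicators] timestep data given but the config has no ",
           "score panels", call. = FALSE)
    }
    panels <- .stage("indicators", {
      stats::setNames(lapply(h$alternatives, function(alt) {
        compute_indicator_panel(ts[ts$alternative == alt, , drop = FALSE],
                                cfg$score_panels[[alt]])
      }), h$alternatives)
    })
    lw <- .stage("indicators", indicator_local_weights(panels))
    contrib <- .stage("synthesize", {
      stats::setNames(lapply(h$alternatives, function(alt) {
        h$global[rownames(lw)] * lw[, alt]
      }), h$alternatives)
    })
    pri <- .stage("synthesize", synthesize_priorities(contrib))
    report$indicators <- panels
    report$local_alternative_weights <- lw
    report$alternatives <- list(totals = pri$totals, ranking = pri$ranking,
                                unit_sum = pri$unit_sum)
  }
  if (!is.null(likert)) {
    lk <- .stage("likert", {
      if (is.character(likert)) read_likert_csv(likert) else likert
    })
    scored <- .stage("likert", score_responses(lk))
    summ <- .stage("likert", summarize_likert(scored))
    sat <- .stage("likert", satisfaction_by_subcriterion(summ))
    report$likert <- summ
    report$satisfaction <- sat
    common <- intersect(names(h$global), names(sat))
    report$gap <- .stage("gap",
      importance_satisfaction(h$global[common], sat[common],
                              thresholds = gap_thresholds))
  }
  if (!is.null(out_dir)) {
    .stage("export", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_report_json(report, file.path(out_dir, "report.json"))
      utils::write.csv(
        data.frame(sub_criterion = names(report$global_weights),
                   global_weight = unname(report$global_weights)),
        file.path(out_dir, "weights.csv"), row.names = FALSE)
      if (!is.null(report$gap)) {
        utils::write.csv(as.data.frame(report$gap),
                         file.path(out_dir, "gap.csv"), row.names = FALSE)
      }
    })
  }
  report
}

#' Write an assessment report as JSON
#'
#' @param report A [run_full_assessment()] report.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
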