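# Run expr under a fixed RNG seed without disturbing the caller's RNG
# stream, so generators are pure functions of (scenario, seed).
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define a synthetic survey scenario
#'
#' Bundles the ground truth from which synthetic studies are generated:
#' per-node true priority vectors, the judgment noise level, the
#' respondent count, per-item true satisfaction means, and per-alternative
#' operational rates for the timestep series.  Together with a seed this
#' fully determines the output of [generate_judgments()],
#' [generate_likert()] and [generate_timesteps()].
#'
#' @param hierarchy A \code{decision_hierarchy}.
#' @param truth Named list of true unit-sum priority vectors, one per node
#'   (\code{"goal"} plus each criterion label), each as long as the node's
#'   child count.
#' @param n_respondents Number of survey respondents (N >= 1).
#' @param judgment_noise Standard deviation of the multiplicative
#'   log-normal perturbation applied to true judgment ratios (log scale,
#'   >= 0).  0 means every respondent reports the rounded true ratio.
#' @param likert_means True per-item mean satisfaction scores in
#'   \code{[1, points]} (named or positional by item id).
#' @param likert_sd Dispersion of the discretized-normal answer
#'   distribution (>= 0; 0 is a point mass at the rounded mean).
#' @param rates Named list (one element per alternative) of operational
#'   rate parameters; see [generate_timesteps()] for the fields.
#' @param points Likert scale width (default 5).
#' @return An object of class \code{survey_scenario}.
#' @seealso [paper_scenario()] for the frozen worked-example scenario.
#' @export
survey_scenario <- function(hierarchy, truth, n_respondents = 80,
                            judgment_noise = 0.3, likert_means = NULL,
                            likert_sd = 0.8, rates = NULL, points = 5) {
  stopifnot(inherits(hierarchy, "decision_hierarchy"))
  nodes <- c("goal", names(hierarchy$criteria))
  miss <- setdiff(nodes, names(truth))
  if (length(miss) > 0) {
    stop("truth vectors missing for node(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nd in nodes) {
    w <- truth[[nd]]
    if (length(w) != length(.node_children(hierarchy, nd)) ||
        any(w <= 0) || abs(sum(w) - 1) > 1e-6) {
      stop("truth for node '", nd,
           "' must be positive, unit-sum, one weight per child",
           call. = FALSE)
    }
  }
  if (n_respondents < 1) stop("need at least one respondent", call. = FALSE)
  if (judgment_noise < 0) stop("judgment noise must be >= 0", call. = FALSE)
  if (!is.null(likert_means) &&
      (any(likert_means < 1) || any(likert_means > points))) {
    stop("likert means must lie in [1, ", points, "]", call. = FALSE)
  }
  if (likert_sd < 0) stop("likert dispersion must be >= 0", call. = FALSE)
  structure(
    list(hierarchy = hierarchy, truth = truth,
         n_respondents = as.integer(n_respondents),
         judgment_noise = judgment_noise,
         likert_means = likert_means, likert_sd = likert_sd,
         rates = rates, points = points),
    class = "survey_scenario"
  )
}

#' The frozen worked-example scenario
#'
#' A "paper-like" synthetic study for the thyroglobulin-assay assessment:
#' the [paper_hierarchy()] (5 criteria, 14 sub-criteria, 3 alternatives),
#' 80 respondents, true priorities equal to the worked example's
#' eigenvector weights at every node, judgment noise 0.3 on the log
#' scale, item satisfaction means that reproduce the reported pattern
#' (high satisfaction with technological safety, staffing, side effects
#' and social respect; low with clinical efficacy, cost adequacy and
#' treatment duration), and operational rates under which the LPG
#' biosensor outperforms cytology on effectiveness and reliability.
#'
#' @param n_respondents Respondent count (default 80, the study size).
#' @param judgment_noise Log-scale judgment noise (default 0.3).
#' @return A [survey_scenario()].
#' @export
paper_scenario <- function(n_respondents = 80, judgment_noise = 0.3) {
  h <- paper_hierarchy()
  truth <- list(
    goal = c(0.0404, 0.0807, 0.4935, 0.2412, 0.1443) /
      sum(c(0.0404, 0.0807, 0.4935, 0.2412, 0.1443)),
    "Technical aspects" = c(3, 3, 1) / 7,
    "Organizational aspects" = c(5, 1) / 6,
    "Economic aspects" = c(0.1140, 0.4054, 0.4806),
    "Clinical aspects" = c(3, 3, 1) / 7,
    "Social, ethical and legal aspects" = c(0.1884, 0.0810, 0.7306)
  )
  base_rates <- list(
    arrival = 12, exec_prob = 0.85, eff_prob = 0.8, fault_rate = 0.3,
    repeat_prob = 0.15, side_prob = 0.05, error_prob = 0.05,
    refusal_surgeon_rate = 0.05, refusal_patient_rate = 0.1,
    revenue_per_exam = 120, mon_margin = 0.2, profit_margin = 0.12,
    specialists = 2, biologists = 2, planned_daily = 12, util = 0.8)
  tweak <- function(...) utils::modifyList(base_rates, list(...))
  survey_scenario(
    hierarchy = h, truth = truth, n_respondents = n_respondents,
    judgment_noise = judgment_noise,
    # satisfaction means: items 3,5,6,7,11 high; 1,2,4,12,13 moderate;
    # 8,9,10 low (the dissatisfaction drivers reported for the case study)
    likert_means = c(3.8, 3.8, 4.3, 3.8, 4.3, 4.3, 4.3, 2.8, 2.8, 2.8,
                     4.3, 3.8, 3.8),
    likert_sd = 0.8,
    rates = list(
      "Cytological Analysis" = tweak(eff_prob = 0.7, fault_rate = 0.5,
                                     repeat_prob = 0.25, mon_margin = 0.15),
      "Biosensor LOF" = tweak(eff_prob = 0.85, fault_rate = 0.2),
      "Biosensor LPG" = tweak(eff_prob = 0.9, fault_rate = 0.15,
                              mon_margin = 0.25)
    )
  )
}

#' Generate synthetic respondent judgments
#'
#' Respondent k's answer for child pair (i, j) at a node is the true
#' ratio \eqn{w_i / w_j} perturbed multiplicatively by
#' \eqn{e^\epsilon, \epsilon \sim N(0, noise^2)}, clamped to
#' \code{[1/9, 9]} and rounded to the Saaty scale — a ratio-scale noise
#' model that keeps each respondent's matrix exactly reciprocal.
#'
#' @param scenario A [survey_scenario()].
#' @param seed Integer seed; same (scenario, seed) always yields the same
#'   table.
#' @return A data frame in the judgments-CSV layout (\code{respondent_id},
#'   \code{node}, \code{child_a}, \code{child_b}, \code{answer}) with one
#'   row per respondent, node and upper-triangle pair.
#' @export
generate_judgments <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "survey_scenario"))
  h <- scenario$hierarchy
  .with_seed(seed, {
    rows <- list()
    for (nd in c("goal", names(h$criteria))) {
      children <- .node_children(h, nd)
      w <- scenario$truth[[nd]]
      n <- length(children)
      if (n < 2) next
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          eps <- stats::rnorm(scenario$n_respondents, 0,
                              scenario$judgment_noise)
          ratio <- pmin(pmax((w[i] / w[j]) * exp(eps), 1 / 9), 9)
          rows[[length(rows) + 1L]] <- data.frame(
            respondent_id = seq_len(scenario$n_respondents),
            node = nd, child_a = children[i], child_b = children[j],
            answer = round_to_saaty(ratio),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    out[order(out$respondent_id), , drop = FALSE]
  })
}

#' Generate synthetic Likert answers
#'
#' Per item, satisfaction scores are drawn from a discretized normal
#' distribution on \code{1..k} with the scenario's true mean and
#' dispersion (dispersion 0 is a point mass at the rounded mean), then
#' emitted as agreement-category labels: reverse-coded items are flipped
#' onto the agreement scale so that scoring them downstream recovers the
#' intended satisfaction.
#'
#' @param scenario A [survey_scenario()] with \code{likert_means} set.
#' @param seed Integer seed.
#' @param codebook A [likert_codebook()] (supplies item ids and reverse
#'   flags).
#' @return A data frame in the Likert-CSV layout (\code{respondent_id},
#'   \code{item_id}, \code{answer}).
#' @export
generate_likert <- function(scenario, seed = 1, codebook = likert_codebook()) {
  stopifnot(inherits(scenario, "survey_scenario"))
  means <- scenario$likert_means
  if (is.null(means)) stop("scenario has no likert means", call. = FALSE)
  if (length(means) != nrow(codebook)) {
    stop("need one mean per codebook item (", nrow(codebook), ")",
         call. = FALSE)
  }
  k <- scenario$points
  cats <- likert_categories(k)
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(codebook)), function(ii) {
      m <- means[ii]
      if (scenario$likert_sd == 0) {
        score <- rep(pmin(pmax(round(m), 1), k), scenario$n_respondents)
      } else {
        edges <- c(-Inf, seq_len(k - 1) + 0.5, Inf)
        p <- diff(stats::pnorm(edges, mean = m, sd = scenario$likert_sd))
        score <- sample.int(k, scenario$n_respondents, replace = TRUE,
                            prob = p)
      }
      # satisfaction score -> agreement label: direct items agree when
      # satisfied, reverse items agree when unsatisfied
      lab_idx <- if (codebook$reverse[ii]) score else k + 1L - score
      data.frame(respondent_id = seq_len(scenario$n_respondents),
                 item_id = codebook$item[ii], answer = cats[lab_idx],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(out$respondent_id, out$item_id), , drop = FALSE]
  })
}

#' Generate a synthetic per-timestep operational series
#'
#' Simulates \code{T} timesteps per alternative: incoming requests are
#' Poisson at the arrival rate; executed, effective, repeated,
#' side-effect and error counts are binomial thinnings of them (so the
#' series is internally consistent, e.g. effective tests never exceed
#' incoming requests); ethical refusals are Poisson at their rates;
#' revenues are executed exams times revenue per exam, with MON and net
#' profit as fixed margins on revenue; staffing and the planned daily
#' load are constants, with the executed daily load a binomial thinning
#' of the plan.
#'
#' Rate fields per alternative: \code{arrival}, \code{exec_prob},
#' \code{eff_prob}, \code{fault_rate}, \code{repeat_prob},
#' \code{side_prob}, \code{error_prob}, \code{refusal_surgeon_rate},
#' \code{refusal_patient_rate}, \code{revenue_per_exam},
#' \code{mon_margin}, \code{profit_margin}, \code{specialists},
#' \code{biologists}, \code{planned_daily}, \code{util}.
#'
#' @param scenario A [survey_scenario()] with \code{rates} set.
#' @param T Number of timesteps (>= 1).
#' @param seed Integer seed.
#' @return A data frame with the [timestep_columns()] layout, \code{T}
#'   rows per alternative.
#' @export
generate_timesteps <- function(scenario, T = 50, seed = 1) {
  stopifnot(inherits(scenario, "survey_scenario"))
  if (is.null(scenario$rates)) stop("scenario has no rates", call. = FALSE)
  if (T < 1) stop("need T >= 1 timesteps", call. = FALSE)
  for (alt in names(scenario$rates)) {
    r <- scenario$rates[[alt]]
    if (any(unlist(r) < 0)) {
      stop("negative rate for alternative '", alt, "'", call. = FALSE)
    }
    if (r$refusal_surgeon_rate + r$refusal_patient_rate > r$arrival) {
      stop("impossible constraint for '", alt,
           "': refusal rates exceed arrival rate", call. = FALSE)
    }
  }
  .with_seed(seed, {
    out <- do.call(rbind, lapply(names(scenario$rates), function(alt) {
      r <- scenario$rates[[alt]]
      incoming <- stats::rpois(T, r$arrival)
      executed <- stats::rbinom(T, incoming, r$exec_prob)
      effective <- stats::rbinom(T, incoming, r$eff_prob)
      repeated <- stats::rbinom(T, executed, r$repeat_prob)
      no_addl <- executed - repeated
      no_invest <- stats::rbinom(T, no_addl, 0.9)
      side <- stats::rbinom(T, executed, r$side_prob)
      err <- stats::rbinom(T, effective, r$error_prob)
      faults <- stats::rpois(T, r$fault_rate)
      ref_s <- stats::rpois(T, r$refusal_surgeon_rate)
      ref_p <- stats::rpois(T, r$refusal_patient_rate)
      revenue <- executed * r$revenue_per_exam
      exec_daily <- stats::rbinom(T, r$planned_daily, r$util)
      data.frame(
        timestep = seq_len(T), alternative = alt,
        executed_exams = executed, queued_exams_for_faults = faults,
        exams_no_additional_withdrawals = no_addl,
        exams_no_further_investigation = no_invest,
        exams_requiring_further_withdrawals = repeated,
        effective_tests = effective, effective_exams_with_error = err,
        exams_with_side_effects = side, incoming_requests = incoming,
        refused_exams_surgeon = ref_s, refused_exams_patient = ref_p,
        net_profit = revenue * r$profit_margin,
        mon = revenue * r$mon_margin, net_revenues = revenue,
        medical_specialists = r$specialists, biologists = r$biologists,
        planned_daily_exams = r$planned_daily,
        executed_daily_exams = exec_daily,
        stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
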