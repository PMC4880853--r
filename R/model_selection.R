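#' Candidate predictor groups for stepwise selection
#'
#' Builds the default candidate roster from a completed dataset: biological
#' factors (gender, race, BMI, age, urinary creatinine), behavioral factors
#' (the categorical smoking variable, log10 cotinine, recent alcohol, recent
#' fish/shellfish) and water-use characteristics (log10 water arsenic as
#' linear and quadratic terms, the four-level water-source category, log10
#' daily tap-water consumption). Continuous predictors enter on the log10
#' scale. Each candidate is a named column group; multi-column groups (the
#' water-source factor) enter and leave the model as a unit.
#'
#' @param data Completed cohort data frame.
#' @param smoking_cutoff Cutoff for [smoking_category()], ng/mg creatinine.
#' @return Named list of numeric matrices, one per candidate.
#' @export
candidate_groups <- function(data, smoking_cutoff = 100) {
  lw <- log10(data$water_tas)
  g <- list(
    female = cbind(female = as.numeric(data$gender == "female")),
    race = cbind(race_other = as.numeric(data$race == "other")),
    log10_bmi = cbind(log10_bmi = log10(data$bmi)),
    log10_age = cbind(log10_age = log10(data$age)),
    log10_creatinine = cbind(log10_creatinine = log10(data$creatinine)),
    smoking_cat = cbind(smoker = as.numeric(
      smoking_category(data$cotinine, data$creatinine, smoking_cutoff) == "smoker")),
    log10_cotinine = cbind(log10_cotinine = log10(data$cotinine)),
    recent_alcohol = cbind(recent_alcohol = as.numeric(data$recent_alcohol)),
    recent_fish = cbind(recent_fish = as.numeric(data$recent_fish)),
    log10_water = cbind(log10_water = lw),
    log10_water_sq = cbind(log10_water_sq = lw^2),
    water_source = cbind(
      src_filtered = as.numeric(data$water_source == "filtered"),
      src_other_treatment = as.numeric(data$water_source == "other_treatment"),
      src_bottled = as.numeric(data$water_source == "bottled")),
    log10_consumption = cbind(
      log10_consumption = log10(recode_water_consumption(data$tap_water_consumption)))
  )
  g
}

# RSS and rank of the least-squares fit of y on cbind(1, columns).
.ls_rss <- function(y, X) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), X)
  qr_ <- qr(X)
  list(rss = sum(qr.resid(qr_, y)^2), rank = qr_$rank, ncol = ncol(X))
}

#' Bidirectional stepwise selection of candidate groups
#'
#' Stepwise linear-model selection over named candidate column groups.
#' Two criteria are available: `"sbc"` (default) adds or removes the group
#' that most improves the Schwarz Bayesian criterion, stopping at a local
#' minimum — the behavior of standard stepwise implementations run with
#' their default criteria; `"p"` uses classical F-test entry/stay thresholds
#' (`alpha_enter`, `alpha_stay`). Interaction candidates (products of two
#' groups) are considered only while both main effects are in the model, and
#' main effects are not removable while a dependent interaction is selected.
#' Candidate groups that are collinear with the current model (no rank
#' increase) are never entered.
#'
#' @param y Response vector.
#' @param groups Named list of candidate matrices ([candidate_groups()]).
#' @param interactions List of character pairs naming interaction candidates,
#'   e.g. `list(c("water_source", "log10_water"))`.
#' @param criterion `"sbc"` or `"p"`.
#' @param alpha_enter,alpha_stay F-test significance thresholds for the
#'   `"p"` criterion.
#' @param max_steps Safety cap on add/drop cycles.
#' @return Character vector of selected candidate names (interactions as
#'   `"a:b"`).
#' @export
stepwise_select <- function(y, groups, interactions = list(),
                            criterion = c("sbc", "p"),
                            alpha_enter = 0.15, alpha_stay = 0.15,
                            max_steps = 100) {
  criterion <- match.arg(criterion)
  n <- length(y)
  all_groups <- groups
  for (pair in interactions) {
    nm <- paste(pair, collapse = ":")
    A <- groups[[pair[1]]]; B <- groups[[pair[2]]]
    cols <- do.call(cbind, lapply(seq_len(ncol(A)), function(i)
      sapply(seq_len(ncol(B)), function(j) A[, i] * B[, j])))
    cols <- matrix(cols, nrow = n)
    colnames(cols) <- as.vector(outer(colnames(A), colnames(B), paste, sep = ":"))
    all_groups[[nm]] <- cols
  }
  main_names <- names(groups)
  int_names <- setdiff(names(all_groups), main_names)
  int_parents <- stats::setNames(lapply(interactions, identity),
                                 vapply(interactions, paste, "", collapse = ":"))

  selected <- character(0)
  model_X <- function(sel) {
    if (!length(sel)) NULL else do.call(cbind, all_groups[sel])
  }
  fit_stats <- function(sel) .ls_rss(y, model_X(sel))
  sbc_of <- function(st) n * log(st$rss / n) + st$rank * log(n)
  eligible_entry <- function(sel) {
    cands <- setdiff(names(all_groups), sel)
    ok_int <- vapply(cands, function(g) {
      if (!(g %in% int_names)) TRUE else all(int_parents[[g]] %in% sel)
    }, logical(1))
    cands[ok_int]
  }
  eligible_drop <- function(sel) {
    sel[vapply(sel, function(g) {
      if (g %in% int_names) return(TRUE)
      deps <- int_names[vapply(int_names, function(i) g %in% int_parents[[i]],
                               logical(1))]
      !any(deps %in% sel)
    }, logical(1))]
  }

  cur <- fit_stats(selected)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # entry phase
    cands <- eligible_entry(selected)
    if (length(cands)) {
      scores <- lapply(cands, function(g) {
        st <- fit_stats(c(selected, g))
        if (st$rank <= cur$rank) return(NULL)  # collinear: never co-selected
        st
      })
      keep <- !vapply(scores, is.null, logical(1))
      cands <- cands[keep]; scores <- scores[keep]
      if (length(cands)) {
        if (criterion == "sbc") {
          vals <- vapply(scores, sbc_of, numeric(1))
          best <- which.min(vals)
          if (vals[best] < sbc_of(cur) - 1e-10) {
            selected <- c(selected, cands[best]); cur <- scores[[best]]
            changed <- TRUE
          }
        } else {
          pvals <- vapply(seq_along(cands), function(i) {
            st <- scores[[i]]
            q <- st$rank - cur$rank
            df2 <- n - st$rank
            if (df2 <= 0 || st$rss <= 0) return(0)
            f <- ((cur$rss - st$rss) / q) / (st$rss / df2)
            stats::pf(f, q, df2, lower.tail = FALSE)
          }, numeric(1))
          best <- which.min(pvals)
          if (pvals[best] < alpha_enter) {
            selected <- c(selected, cands[best]); cur <- fit_stats(selected)
            changed <- TRUE
          }
        }
      }
    }
    # removal phase
    drops <- eligible_drop(selected)
    if (length(drops)) {
      if (criterion == "sbc") {
        vals <- vapply(drops, function(g) sbc_of(fit_stats(setdiff(selected, g))),
                       numeric(1))
        best <- which.min(vals)
        if (vals[best] < sbc_of(cur) - 1e-10) {
          selected <- setdiff(selected, drops[best]); cur <- fit_stats(selected)
          changed <- TRUE
        }
      } else {
        pvals <- vapply(drops, function(g) {
          st0 <- fit_stats(setdiff(selected, g))
          q <- cur$rank - st0$rank
          df2 <- n - cur$rank
          if (q <= 0) return(0)
          f <- ((st0$rss - cur$rss) / q) / (cur$rss / df2)
          stats::pf(f, q, df2, lower.tail = FALSE)
        }, numeric(1))
        worst <- which.max(pvals)
        if (pvals[worst] > alpha_stay) {
          selected <- setdiff(selected, drops[worst]); cur <- fit_stats(selected)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  selected
}

#' Stepwise selection across dependent variables and imputations
#'
#' Runs [stepwise_select()] for every combination of dependent variable and
#' completed dataset (by default 9 x M runs) and tallies how often each
#' candidate is selected. Runs that fail (e.g. singular designs) are skipped
#' with a warning and reduce the total.
#'
#' @param mi An `mi_cohort` with derived columns.
#' @param dependents Dependent-variable column names
#'   (default [dependent_variables()]).
#' @param candidates Function building candidate groups from a dataset
#'   (default [candidate_groups()]).
#' @param interactions Interaction candidates, as in [stepwise_select()].
#' @param ... Passed to [stepwise_select()] (`criterion`, `alpha_enter`, ...).
#' @return Object of class `selection_tally`: data frame (`candidate`,
#'   `count`) with attributes `total_runs` and `runs_failed`.
#' @export
run_stepwise <- function(mi, dependents = dependent_variables(),
                         candidates = candidate_groups,
                         interactions = list(c("water_source", "log10_water")),
                         ...) {
  counts <- NULL
  total <- 0L
  failed <- 0L
  for (im in seq_len(mi$m)) {
    d <- mi$datasets[[im]]
    groups <- candidates(d)
    if (is.null(counts)) {
      cand_names <- c(names(groups),
                      vapply(interactions, paste, "", collapse = ":"))
      counts <- stats::setNames(integer(length(cand_names)), cand_names)
    }
    for (dep in dependents) {
      sel <- tryCatch(
        stepwise_select(d[[dep]], groups, interactions = interactions, ...),
        error = function(e) {
          warning("stepwise run skipped (", dep, ", imputation ", im, "): ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(sel)) { failed <- failed + 1L; next }
      total <- total + 1L
      counts[sel] <- counts[sel] + 1L
    }
  }
  structure(data.frame(candidate = names(counts), count = unname(counts)),
            total_runs = total, runs_failed = failed,
            class = c("selection_tally", "data.frame"))
}

#' Retain candidates selected often enough
#'
#' A candidate is retained when selected in strictly more than `threshold`
#' of the runs (default more than 25 of the 180 dependent-by-imputation
#' combinations).
#'
#' @param tally A `selection_tally` from [run_stepwise()].
#' @param threshold Strict count threshold.
#' @return Character vector of retained candidate names.
#' @export
retain_predictors <- function(tally, threshold = 25) {
  total <- attr(tally, "total_runs")
  if (!is.null(total) && threshold >= total)
    stop("threshold must be below the total number of runs")
  tally$candidate[tally$count > threshold]
}

#' Post-selection revision of the retained predictor set
#'
#' Applies the review rules used to turn the raw retained set into the final
#' model terms: (i) when both the categorical smoking variable and log10
#' cotinine are retained, only log10 cotinine is kept (it predicted more
#' dependent variables); (ii) any combination of water-arsenic and
#' water-source/treatment candidates is replaced by the interaction structure
#' of drinking-water source with transformed water arsenic (per-source
#' intercepts and slopes); (iii) the recent fish/shellfish indicator is
#' forced into the model even when selected rarely.
#'
#' @param retained Character vector from [retain_predictors()].
#' @return Character vector of final model terms; the water structure appears
#'   as `"water_source_x_tas"`.
#' @export
revise_selection <- function(retained) {
  out <- retained
  if (all(c("smoking_cat", "log10_cotinine") %in% out))
    out <- setdiff(out, "smoking_cat")
  water_related <- c("log10_water", "log10_water_sq", "water_source",
                     "water_source:log10_water", "log10_water:water_source")
  out <- setdiff(out, water_related)
  out <- union(out, "water_source_x_tas")
  out <- union(out, "recent_fish")
  out
}
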