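#' Pipeline configuration
#'
#' @param seed Master seed; stage seeds are derived deterministically from
#'   it so stages can be re-run independently.
#' @param cohort Either `"synthetic"` (generate from `specs`), a path to a
#'   cohort CSV, or a data.frame.
#' @param specs Cluster specifications for the synthetic route (default the
#'   published three-cluster profiles, [kdt_published_clusters()]).
#' @param sampler List: `method` (`"hierarchical"` or `"mle"`), `chains`,
#'   `n_samples`, `burn_in`.
#' @param k_range Candidate cluster counts (default 2:6).
#' @param alpha Significance level (default 0.05).
#' @param out_dir Output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, cohort = "synthetic",
                            specs = kdt_published_clusters(),
                            sampler = list(method = "hierarchical",
                                           chains = 3L, n_samples = 2000L,
                                           burn_in = 1000L),
                            k_range = 2:6, alpha = 0.05,
                            out_dir = tempfile("kdt_run_")) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(seed = as.integer(seed), cohort = cohort, specs = specs,
                 sampler = sampler, k_range = k_range, alpha = alpha,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes all stages in order — generate (or load) the cohort, simulate
#' and fit mixed-gamble choices, simulate and score Iowa-gambling sessions,
#' draw questionnaire totals, build the covariate-controlled correlation
#' table, cluster the behavioral profiles (Ward + silhouette + K-means
#' confirmation), and compare clusters on the classical measures
#' (MANCOVA + Bonferroni post hocs) — writing every artifact plus a JSON
#' run manifest into `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `choices`, `fit`, `correlations`, `clusters`, `profiles`,
#'   `comparison`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }

  cohort <- stage("cohort", {
    if (is.data.frame(config$cohort)) config$cohort
    else if (identical(config$cohort, "synthetic")) {
      co <- generate_profiles(config$specs, seed = child_seed(config$seed, 1))
      set.seed(child_seed(config$seed, 2))
      co$gender <- stats::rbinom(nrow(co), 1, 0.5)
      co$videogame_ability <- sample(1:5, nrow(co), replace = TRUE)
      simulate_questionnaires(co, seed = child_seed(config$seed, 3),
                              fields = "useq_total")
    } else utils::read.csv(config$cohort)
  })
  n <- nrow(cohort)

  choices <- stage("simulate_mgt", {
    gm <- build_gamble_matrix()
    if (!all(c("true_rho", "true_lambda", "true_mu") %in% names(cohort)))
      stop("cohort lacks generative PT parameters for choice simulation")
    do.call(rbind, lapply(seq_len(n), function(i) {
      d <- simulate_mgt_choices(
        pt_params(cohort$true_rho[i], cohort$true_lambda[i],
                  cohort$true_mu[i]),
        gm, seed = child_seed(config$seed, 100 + i))
      cbind(subject = cohort$participant[i], d)
    }))
  })

  fit <- stage("fit_mgt", {
    if (identical(config$sampler$method, "mle")) {
      est <- do.call(rbind, lapply(split(choices, choices$subject),
        function(d) {
          f <- fit_pt_mle(d, seed = child_seed(config$seed, 4))
          data.frame(subject = d$subject[1], rho_mean = f$params[["rho"]],
                     lambda_mean = f$params[["lambda"]],
                     mu_mean = f$params[["mu"]])
        }))
      list(subject_summary = est, group_summary = NULL, method = "mle")
    } else {
      fit_pt_hierarchical(choices, chains = config$sampler$chains,
                          n_samples = config$sampler$n_samples,
                          burn_in = config$sampler$burn_in,
                          seed = child_seed(config$seed, 4))
    }
  })
  idx <- match(cohort$participant, fit$subject_summary$subject)
  cohort$rho <- fit$subject_summary$rho_mean[idx]
  cohort$lambda <- fit$subject_summary$lambda_mean[idx]
  cohort$mu <- fit$subject_summary$mu_mean[idx]

  cohort <- stage("score_igt", {
    if (!"ig_index" %in% names(cohort)) {
      cohort$ig_index <- vapply(seq_len(n), function(i)
        ig_index(simulate_igt_choices(seed = child_seed(config$seed,
                                                        200 + i))),
        integer(1))
    }
    cohort
  })

  classical_vars <- intersect(c("rho", "lambda", "mu", "ig_index",
                                "stimulating_risk", "instrumental_risk"),
                              names(cohort))
  covars <- intersect(c("gender", "videogame_ability"), names(cohort))
  if (length(covars) == 0L) covars <- NULL

  correlations <- stage("correlate",
    correlation_table(cohort, kdt_variables(), classical_vars,
                      covariates = covars, alpha = config$alpha))

  clusters <- stage("cluster", {
    z <- zscore_table(cohort, kdt_variables())
    choose_k(z, ward_cluster(z), k_range = config$k_range,
             seed = child_seed(config$seed, 5))
  })
  lab <- clusters$labels[, paste0("k", clusters$chosen_k)]
  profiles <- characterize_clusters(cohort, lab)
  cohort$cluster <- unname(profiles[as.character(lab)])

  comparison <- stage("compare",
    mancova(cohort[classical_vars], cohort$cluster,
            covariates = if (is.null(covars)) NULL else cohort[covars],
            alpha = config$alpha))

  manifest <- list(seed = config$seed, alpha = config$alpha,
                   sampler = config$sampler,
                   k_range = config$k_range,
                   n_participants = n,
                   chosen_k = clusters$chosen_k,
                   cluster_profiles = as.list(profiles),
                   r_version = as.character(getRversion()),
                   timings_sec = timings)
  p <- function(f) file.path(config$out_dir, f)
  write_cohort(cohort, p("cohort.csv"),
               config = list(seed = config$seed, source = "run_pipeline"))
  utils::write.csv(choices, p("mgt_choices.csv"), row.names = FALSE)
  utils::write.csv(fit$subject_summary, p("posterior_summary.csv"),
                   row.names = FALSE)
  write_correlation_table(correlations, p("correlation_table.csv"))
  write_cluster_solution(clusters, p("cluster_solution.json"))
  write_group_comparison(comparison, p("group_comparison.csv"),
                         p("group_comparison.json"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(cohort = cohort, choices = choices, fit = fit,
                 correlations = correlations, clusters = clusters,
                 profiles = profiles, comparison = comparison,
                 manifest = manifest))
}

#' Validate a cohort CSV against the behavioral schema
#'
#' Checks that the 18 KDT variables are present, numeric, non-missing, and
#' non-negative integers (they are event counts).
#'
#' @param path Path to a cohort CSV.
#' @return Data.frame of issues (`row`, `column`, `issue`); zero rows when
#'   the file conforms.
#' @export
validate_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  co <- utils::read.csv(path)
  issues <- data.frame(row = integer(0), column = character(0),
                       issue = character(0))
  add <- function(row, col, what)
    issues <<- rbind(issues,
                     data.frame(row = row, column = col, issue = what))
  for (v in kdt_variables()) {
    if (!v %in% names(co)) {
      add(NA_integer_, v, "missing column")
      next
    }
    x <- co[[v]]
    if (!is.numeric(x)) { add(NA_integer_, v, "non-numeric column"); next }
    for (r in which(is.na(x))) add(r, v, "missing value")
    for (r in which(!is.na(x) & x < 0)) add(r, v, "negative count")
    for (r in which(!is.na(x) & x != round(x)))
      add(r, v, "non-integer count")
  }
  issues
}
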