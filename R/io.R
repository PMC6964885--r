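# File formats and the end-to-end pipeline driver. CSV dialect: UTF-8,
# comma-separated, '.' decimal; respondent ids are opaque strings.

#' Write respondent choices to long-format CSV
#'
#' Columns: `respondent_id, version, task, alternative_chosen, is_warmup`.
#' Warm-up answers (if present) are written with `is_warmup = 1` and task
#' numbers restarting at 1.
#'
#' @param choices a `respondent_choices` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_choices <- function(choices, path) {
  stopifnot(inherits(choices, "respondent_choices"))
  n <- nrow(choices$main); nt <- ncol(choices$main)
  df <- data.frame(
    respondent_id = rep(choices$ids, each = nt),
    version = rep(choices$version, each = nt),
    task = rep(seq_len(nt), n),
    alternative_chosen = as.integer(t(choices$main)),
    is_warmup = 0L
  )
  if (!is.null(choices$warmup)) {
    nw <- ncol(choices$warmup)
    df <- rbind(df, data.frame(
      respondent_id = rep(choices$ids, each = nw),
      version = rep(choices$version, each = nw),
      task = rep(seq_len(nw), n),
      alternative_chosen = as.integer(t(choices$warmup)),
      is_warmup = 1L
    ))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read respondent choices from long-format CSV
#'
#' Validates against the design: duplicate `(respondent, task)` rows, unknown
#' design versions and out-of-range alternatives are errors naming the
#' offending row numbers.
#'
#' @param path CSV written by [write_choices()] (header `respondent_id,
#'   version, task, alternative_chosen, is_warmup`).
#' @param design the `choice_design` the respondents answered.
#' @return a `respondent_choices` object.
#' @export
read_choices <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "version", "task", "alternative_chosen", "is_warmup")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad_v <- which(df$version < 1L | df$version > design$n_versions)
  if (length(bad_v)) {
    stop("unknown design version in rows: ", paste(utils::head(bad_v, 5L), collapse = ", "))
  }
  bad_a <- which(df$alternative_chosen < 1L |
                 df$alternative_chosen > design$n_alts)
  if (length(bad_a)) {
    stop("chosen alternative out of range in rows: ",
         paste(utils::head(bad_a, 5L), collapse = ", "))
  }
  key <- paste(df$respondent_id, df$is_warmup, df$task)
  if (anyDuplicated(key)) {
    stop("duplicate (respondent, task) rows: ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  }
  ids <- unique(df$respondent_id)
  main_df <- df[df$is_warmup == 0L, ]
  nt <- max(main_df$task)
  if (nt != design$n_tasks) stop("task count does not match the design")
  main <- matrix(NA_integer_, length(ids), nt)
  version <- integer(length(ids))
  for (i in seq_along(ids)) {
    ri <- main_df[main_df$respondent_id == ids[i], ]
    if (nrow(ri) != nt) stop("respondent ", ids[i], " has ", nrow(ri),
                             " main tasks, expected ", nt)
    main[i, ri$task] <- ri$alternative_chosen
    version[i] <- ri$version[1L]
  }
  warm <- NULL
  warm_df <- df[df$is_warmup == 1L, ]
  if (nrow(warm_df) > 0L) {
    nw <- max(warm_df$task)
    warm <- matrix(NA_integer_, length(ids), nw)
    for (i in seq_along(ids)) {
      ri <- warm_df[warm_df$respondent_id == ids[i], ]
      warm[i, ri$task] <- ri$alternative_chosen
    }
  }
  respondent_choices(main, version, warm, design$n_alts, ids = ids)
}

#' Write / read an attribute schema as JSON
#'
#' @param schema an [attribute_schema()].
#' @param path JSON file path.
#' @return `write_schema`: `path` invisibly; `read_schema`: the schema.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "attribute_schema"))
  out <- lapply(schema$attributes, function(a) {
    list(name = a$name, kind = a$kind, levels = a$levels,
         ordering = a$ordering, center = a$center)
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  attrs <- lapply(seq_len(nrow(raw)), function(i) {
    attribute(raw$name[i], raw$kind[i], unlist(raw$levels[i]),
              raw$ordering[i],
              center = if (!is.null(raw$center)) raw$center[i])
  })
  attribute_schema(attrs)
}

#' Write a choice design to long-format CSV
#'
#' One row per (version, task, alternative); one column per attribute
#' holding the level index.
#'
#' @param design a `choice_design`.
#' @param schema the matching schema (for attribute column names).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, schema, path) {
  nv <- design$n_versions; nt <- design$n_tasks; na <- design$n_alts
  grid <- expand.grid(alternative = seq_len(na), task = seq_len(nt),
                      version = seq_len(nv))
  lev <- sapply(seq_len(n_attributes(schema)), function(k) {
    cube <- array(design$cells[, , , k], dim = c(nv, nt, na))
    as.integer(aperm(cube, c(3L, 2L, 1L)))  # alternative varies fastest
  })
  colnames(lev) <- names(schema$attributes)
  df <- cbind(grid[, c("version", "task", "alternative")], lev)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Executes design generation, population simulation, choice simulation,
#' hierarchical Bayes estimation, posterior summaries, latent-class
#' analysis, internal-validity audits and the treatment-scenario engine in
#' order, writing every stage's outputs under `out_dir` plus a JSON run
#' manifest (settings, per-stage seeds, convergence summary, file
#' checksums). One global seed deterministically spawns per-stage seeds, so
#' re-running with the same configuration reproduces every output file
#' byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed.
#' @param schema attribute schema (default [crohn_schema()]).
#' @param pop_spec population specification (default
#'   [default_population_spec()]).
#' @param n_versions,n_tasks,n_alts,overlap_target design settings.
#' @param n_warmups warm-up tasks with a dominated alternative.
#' @param mcmc an [mcmc_settings()] profile (its seed is overridden by the
#'   spawned stage seed).
#' @param lc_classes latent-class counts to fit and compare.
#' @param lc_starts EM restarts per class count.
#' @param scenario_draws draws for the treatment-scenario engine.
#' @param scenario scenario name for [apply_sensitivity()].
#' @param profiles treatment profiles (default [crohn_treatment_profiles()]).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         schema = crohn_schema(),
                         pop_spec = default_population_spec(),
                         n_versions = 100L, n_tasks = 13L, n_alts = 3L,
                         overlap_target = 0.7, n_warmups = 2L,
                         mcmc = mcmc_settings(n_burnin = 1000L,
                                              n_monitor = 2000L, thin = 2L),
                         lc_classes = c(1L, 2L), lc_starts = 5L,
                         scenario_draws = 2000L, scenario = "base",
                         profiles = crohn_treatment_profiles()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(seed, 7L)
  names(seeds) <- c("design", "warmups", "population", "choices", "hb", "lc",
                    "scenarios")
  coding <- coding_map(schema)
  files <- character(0L)
  emit <- function(name) files <<- c(files, file.path(out_dir, name))

  design <- generate_design(schema, n_versions, n_tasks, n_alts,
                            overlap_target, seed = seeds[["design"]])
  design$warmups <- make_warmups(schema, n_warmups, n_alts,
                                 seed = seeds[["warmups"]])
  write_design(design, schema, file.path(out_dir, "design.csv")); emit("design.csv")
  jsonlite::write_json(unclass(design$audit),
                       file.path(out_dir, "design_audit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit("design_audit.json")

  prefs <- simulate_population(pop_spec, seed = seeds[["population"]])
  jsonlite::write_json(
    list(class = prefs$class, behavior = prefs$behavior,
         beta = unname(as.data.frame(prefs$beta))),
    file.path(out_dir, "ground_truth.json"), digits = NA, pretty = TRUE)
  emit("ground_truth.json")

  choices <- simulate_choices(design, prefs, schema, coding,
                              seed = seeds[["choices"]])
  write_choices(choices, file.path(out_dir, "choices.csv")); emit("choices.csv")

  mcmc$seed <- seeds[["hb"]]
  post <- fit_hb(choices, design, schema, coding, mcmc)
  gr <- gelman_rubin(post)
  su <- scale_utilities(post, schema, coding)
  ri <- relative_importance(post, schema, coding)
  mt <- mrs_table(post, schema, coding)
  utils::write.csv(su$table, file.path(out_dir, "scaled_utilities.csv"),
                   row.names = FALSE); emit("scaled_utilities.csv")
  utils::write.csv(ri$table, file.path(out_dir, "relative_importance.csv"),
                   row.names = FALSE); emit("relative_importance.csv")
  utils::write.csv(mt, file.path(out_dir, "mrs.csv"), row.names = FALSE)
  emit("mrs.csv")

  lc_fits <- lapply(lc_classes, function(k) {
    fit_lc(choices, design, schema, coding, k, n_starts = lc_starts,
           seed = seeds[["lc"]] %% 100000L + k)
  })
  cmp <- data.frame(
    n_classes = lc_classes,
    loglik = vapply(lc_fits, `[[`, numeric(1L), "loglik"),
    q = vapply(lc_fits, `[[`, numeric(1L), "q"),
    bic = vapply(lc_fits, `[[`, numeric(1L), "bic")
  )
  utils::write.csv(cmp, file.path(out_dir, "lc_model_comparison.csv"),
                   row.names = FALSE); emit("lc_model_comparison.csv")
  best_lc <- lc_fits[[which.min(cmp$bic)]]
  utils::write.csv(
    data.frame(respondent = choices$ids, best_lc$membership),
    file.path(out_dir, "lc_membership.csv"), row.names = FALSE)
  emit("lc_membership.csv")

  vr <- validity_report(choices, design, schema)
  jsonlite::write_json(
    list(warmup_failure_rate = vr$warmup_failure_rate,
         position_shares = vr$position$position_shares,
         n_straightliners = vr$position$n_flagged,
         dominance_per_attribute = as.list(vr$dominance$per_attribute),
         n_dominant = vr$dominance$n_dominant),
    file.path(out_dir, "validity.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  emit("validity.json")

  profs <- apply_sensitivity(profiles, scenario)
  pair_seed_menu <- spawn_seeds(seeds[["scenarios"]], 2L)
  menu <- simulate_menu(profs, post, schema, coding, scenario_draws,
                        seed = pair_seed_menu[1L])
  pairs <- simulate_pairs(profs, post, schema, coding, scenario_draws,
                          seed = pair_seed_menu[2L])
  utils::write.csv(as.data.frame(pairs), file.path(out_dir, "pairwise.csv"))
  emit("pairwise.csv")
  utils::write.csv(data.frame(respondent = choices$ids, menu$prob),
                   file.path(out_dir, "patient_probabilities.csv"),
                   row.names = FALSE); emit("patient_probabilities.csv")
  jsonlite::write_json(
    list(modal_share = as.list(menu$modal_share),
         mean_prob = as.list(menu$mean_prob),
         n_extrapolated = menu$n_extrapolated),
    file.path(out_dir, "cohort_summary.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  emit("cohort_summary.json")

  manifest <- list(
    package_version = as.character(utils::packageVersion("dcepref")),
    global_seed = as.integer(seed),
    stage_seeds = as.list(seeds),
    scenario = scenario,
    mcmc = unclass(mcmc),
    max_psrf = gr$max,
    psrf_pass = gr$pass,
    mean_acceptance = mean(post$accept_rate),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
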