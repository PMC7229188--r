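#' Study configuration
#'
#' Builds (with defaults), validates, reads and writes the configuration
#' driving [run_study()].  A config fully describes a study run: either
#' paths to existing panels/atlas/trials, or the synthetic scenario to
#' simulate in their place, plus every analysis parameter and the master
#' seed.  Configs round-trip through YAML.
#'
#' @param ... named fields overriding the defaults, see
#'   `study_config()$<field>` for the full list.  Key groups:
#'   `out_dir`; data paths (`atlas_path`, `panel_dir`, `trials_path`; all
#'   `NULL` to simulate); simulation block (`n_subjects_per_group`,
#'   `n_nodes`, `n_blocks`, `samples_per_block`, `rho_within`,
#'   `rho_between`, `noise_sd`, `n_systems`); analysis parameters
#'   (`gamma`, `omega_same`, `omega_diff`, `n_runs`, `n_null`, `n_opt`,
#'   `n_perm`, `hrf_peak_s`, `hrf_undershoot_s`, `hrf_ratio`,
#'   `hrf_length_s`, `tr_seconds`); design labels (`sessions`, `groups`,
#'   `conditions`); `seed`.
#' @return object of class `study_config` (a named list).
#' @export
study_config <- function(...) {
  defaults <- list(
    out_dir = "netreconfig_out",
    atlas_path = NULL, panel_dir = NULL, trials_path = NULL,
    n_subjects_per_group = 2L, n_nodes = 24L, n_systems = 4L,
    n_blocks = 20L, samples_per_block = 15L,
    rho_within = 0.6, rho_between = 0.05, noise_sd = 1,
    tr_seconds = 2,
    gamma = 1, omega_same = 1, omega_diff = 0.5,
    n_runs = 20L, n_null = 10L, n_opt = 10L, n_perm = 100L,
    hrf_peak_s = 6, hrf_undershoot_s = 16, hrf_ratio = 6,
    hrf_length_s = 32,
    sessions = c("Naive", "Late"),
    groups = c("experimental", "control"),
    conditions = c("1-back", "2-back"),
    seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, override)
  for (f in c("n_subjects_per_group", "n_nodes", "n_systems", "n_blocks",
              "samples_per_block", "n_runs", "n_null", "n_opt", "n_perm"))
    check_count(cfg[[f]], f)
  for (p in c("atlas_path", "panel_dir", "trials_path"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("config path '", p, "' does not exist: ", cfg[[p]])
  class(cfg) <- "study_config"
  cfg
}

#' @rdname study_config
#' @param path YAML file path.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' @rdname study_config
#' @param config a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Polynomial rolling hash (mod 2^31) used to stamp outputs with their
# config contents.
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(txt)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a full study analysis
#'
#' Orchestrates the pipeline for every subject x session: load or
#' simulate the ROI panel; per task condition, build HRF-weighted
#' connectivity and normalized static modularity; build the block-wise
#' multilayer network, run the multilayer optimization ensemble,
#' summarize it into an allegiance matrix and permutation-normalized
#' recruitment/integration; score behavior; and compute group/session
#' contrasts.  All outputs are written under `config$out_dir`
#' (one directory per subject x session plus study-level summary tables),
#' stamped with the config hash and master seed, and every random stage
#' uses a seed derived from the master seed, so a re-run with an
#' identical config reproduces every number.
#'
#' @param config a [study_config()].
#' @param verbose print per-stage progress (default `TRUE`).
#' @return (invisibly) a list with `modularity` (subject x session x
#'   condition static results), `cartography` (long table),
#'   `behavior` (per-subject d-prime table), `contrasts`
#'   (a [contrast_tables()] report), and `out_dir`.
#' @export
run_study <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  t_start <- Sys.time()
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (verbose) message(msg)
  }
  log_line("run_study start; config hash ", hash, "; seed ", config$seed)
  write_study_config(config, file.path(config$out_dir, "config.yaml"))

  subjects <- data.frame(
    subject = paste0("sub_", seq_len(config$n_subjects_per_group *
                                       length(config$groups))),
    group = rep(config$groups, each = config$n_subjects_per_group),
    stringsAsFactors = FALSE)
  atlas <- if (!is.null(config$atlas_path)) read_atlas(config$atlas_path)
           else system_atlas(rep(paste0("system_",
                                        seq_len(config$n_systems)),
                                 length.out = config$n_nodes))
  hrf <- canonical_hrf(config$tr_seconds, config$hrf_peak_s,
                       config$hrf_undershoot_s, config$hrf_ratio,
                       config$hrf_length_s)
  cells <- expand.grid(subject = subjects$subject,
                       session = config$sessions,
                       stringsAsFactors = FALSE)
  cell_seeds <- derive_seeds(config$seed, nrow(cells) + 1L)

  mod_rows <- list()
  cart_rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sub <- cells$subject[ci]
    ses <- cells$session[ci]
    grp <- subjects$group[match(sub, subjects$subject)]
    cell_dir <- file.path(config$out_dir, sub, ses)
    dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)
    t_cell <- Sys.time()
    panel <- tryCatch({
      if (!is.null(config$panel_dir)) {
        read_panel(file.path(config$panel_dir, paste0(sub, "_", ses)),
                   tr_seconds = config$tr_seconds)
      } else {
        spec <- scenario_spec(
          n_nodes = nrow(atlas), atlas = atlas,
          n_blocks = config$n_blocks,
          samples_per_block = config$samples_per_block,
          rho_within = config$rho_within,
          rho_between = config$rho_between,
          noise_sd = config$noise_sd, tr_seconds = config$tr_seconds,
          seed = cell_seeds[ci])
        generate_panel(spec)
      }
    }, error = function(e) {
      stop("panel stage failed for ", sub, "/", ses, ": ",
           conditionMessage(e))
    })
    stage_seeds <- derive_seeds(cell_seeds[ci], length(config$conditions) + 2L)
    for (ki in seq_along(config$conditions)) {
      cond <- config$conditions[ki]
      res <- tryCatch({
        A <- condition_connectivity(panel, cond, hrf = hrf)
        normalized_modularity(A, gamma = config$gamma,
                              n_runs = config$n_runs,
                              n_null = config$n_null,
                              seed = stage_seeds[ki])
      }, error = function(e) {
        stop("static modularity failed for ", sub, "/", ses, "/", cond,
             ": ", conditionMessage(e))
      })
      write_partition(res$partition, atlas$roi_id,
                      file.path(cell_dir,
                                paste0("partition_", cond, ".tsv")))
      mod_rows[[length(mod_rows) + 1L]] <- data.frame(
        subject = sub, group = grp, session = ses, condition = cond,
        Q = res$Q, Q_normalized = res$Q_normalized,
        n_modules = length(unique(res$partition)),
        config_hash = hash, seed = stage_seeds[ki],
        stringsAsFactors = FALSE)
    }
    cart <- tryCatch({
      stack <- block_connectivity(panel, hrf = hrf)
      net <- multilayer_network(stack, gamma = config$gamma,
                                omega_same = config$omega_same,
                                omega_diff = config$omega_diff)
      ens <- run_ensemble(net, n_opt = config$n_opt,
                          seed = stage_seeds[length(config$conditions) + 1L])
      P <- allegiance(ens)
      write_assignment(ens[[1L]],
                       file.path(cell_dir, "assignment_opt1.tsv"))
      permutation_normalize(P, atlas, n_perm = config$n_perm,
                            seed = stage_seeds[length(config$conditions) + 2L])
    }, error = function(e) {
      stop("multilayer/cartography failed for ", sub, "/", ses, ": ",
           conditionMessage(e))
    })
    cart_df <- as.data.frame(cart)
    cart_df$subject <- sub
    cart_df$group <- grp
    cart_df$session <- ses
    cart_df$config_hash <- hash
    cart_rows[[length(cart_rows) + 1L]] <- cart_df
    write.table(cart_df, file.path(cell_dir, "cartography.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(sub, "/", ses, " done in ",
             round(as.numeric(difftime(Sys.time(), t_cell, units = "secs")),
                   1), " s")
  }
  modularity_tab <- do.call(rbind, mod_rows)
  cartography_tab <- do.call(rbind, cart_rows)

  trials <- if (!is.null(config$trials_path)) {
    read.table(config$trials_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  } else {
    behav_seeds <- derive_seeds(cell_seeds[nrow(cells) + 1L],
                                length(config$groups))
    do.call(rbind, lapply(seq_along(config$groups), function(gi) {
      tt <- simulate_trial_table(
        n_subjects = config$n_subjects_per_group,
        sessions = config$sessions, conditions = config$conditions,
        hit_end = if (gi == 1L) 0.9 else 0.8,
        group = config$groups[gi], seed = behav_seeds[gi])
      tt$subject <- paste0("sub_", (gi - 1L) * config$n_subjects_per_group +
                             as.integer(sub("sub_", "", tt$subject)))
      tt
    }))
  }
  behavior_tab <- subject_dprime(trials)
  contrasts <- contrast_tables(modularity_tab, cartography_tab,
                               behavior_tab,
                               from = config$sessions[1L],
                               to = config$sessions[length(config$sessions)])
  write.table(modularity_tab,
              file.path(config$out_dir, "modularity_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cartography_tab,
              file.path(config$out_dir, "cartography_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(behavior_tab,
              file.path(config$out_dir, "behavior_dprime.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(contrasts$tests,
              file.path(config$out_dir, "contrast_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("run_study finished in ",
           round(as.numeric(difftime(Sys.time(), t_start, units = "secs")),
                 1), " s")
  invisible(list(modularity = modularity_tab,
                 cartography = cartography_tab,
                 behavior = behavior_tab, contrasts = contrasts,
                 out_dir = config$out_dir))
}

#' Group / session contrast tables
#'
#' The simple statistical layer over the pipeline's outputs: paired
#' t-tests across sessions within each group (per measure and condition),
#' two-sample t-tests between groups on the session change scores, and
#' Pearson correlations between the change in each network measure and
#' the change in d-prime.  Raw p-values are adjusted per test family with
#' both Bonferroni and Benjamini-Hochberg corrections.
#'
#' @param modularity data.frame with columns `subject`, `group`,
#'   `session`, `condition`, `Q_normalized` (as produced by
#'   [run_study()]).
#' @param cartography long cartography table with columns `subject`,
#'   `group`, `session`, `measure`, `system_k`, `system_l`, `normalized`;
#'   may be `NULL`.
#' @param behavior [subject_dprime()] output; may be `NULL` (correlations
#'   are then skipped).
#' @param from,to the two sessions contrasted (baseline, endpoint).
#' @return object of class `contrast_report`: list with `tests` (long
#'   data.frame: family, measure, condition/system, group, statistic, df,
#'   p, p_bonferroni, p_BH) and `cells` (cell means).
#' @export
contrast_tables <- function(modularity, cartography = NULL,
                            behavior = NULL, from = "Naive",
                            to = "Late") {
  measures <- long_measures(modularity, cartography)
  change <- measure_change(measures, from, to)
  cells <- aggregate(value ~ measure + group + session,
                     data = measures, FUN = mean)
  tests <- list()
  # paired t-tests within group: session `from` vs `to`
  for (m in unique(change$measure)) {
    for (g in unique(change$group)) {
      d <- change[change$measure == m & change$group == g, ]
      if (nrow(d) < 2L) next
      if (sd(d$delta) == 0) {
        # no variance in the change scores: a null contrast when the
        # change is identically zero, degenerate (NA) otherwise
        zero <- all(d$delta == 0)
        tests[[length(tests) + 1L]] <- data.frame(
          family = "paired_session", measure = m, group = g,
          statistic = if (zero) 0 else NA_real_,
          df = nrow(d) - 1, estimate = mean(d$delta),
          p = if (zero) 1 else NA_real_, stringsAsFactors = FALSE)
        next
      }
      tt <- t.test(d$delta)
      tests[[length(tests) + 1L]] <- data.frame(
        family = "paired_session", measure = m, group = g,
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        estimate = mean(d$delta), p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  # two-sample t-tests between groups on change scores
  groups <- unique(change$group)
  if (length(groups) == 2L) {
    for (m in unique(change$measure)) {
      d <- change[change$measure == m, ]
      a <- d$delta[d$group == groups[1L]]
      b <- d$delta[d$group == groups[2L]]
      if (length(a) < 2L || length(b) < 2L) next
      if (sd(a) == 0 && sd(b) == 0) next
      tt <- t.test(a, b)
      tests[[length(tests) + 1L]] <- data.frame(
        family = "group_change", measure = m, group = "between",
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        estimate = mean(a) - mean(b), p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  # brain-behavior correlations on change scores
  if (!is.null(behavior)) {
    bchange <- measure_change(
      data.frame(subject = behavior$subject, group = behavior$group,
                 session = behavior$session,
                 measure = paste0("dprime|", behavior$condition),
                 value = behavior$dprime, stringsAsFactors = FALSE),
      from, to)
    bwide <- aggregate(delta ~ subject, data = bchange, FUN = mean)
    for (m in unique(change$measure)) {
      d <- merge(change[change$measure == m, ], bwide, by = "subject",
                 suffixes = c("_measure", "_dprime"))
      if (nrow(d) < 3L) next
      if (sd(d$delta_measure) == 0 || sd(d$delta_dprime) == 0) next
      ct <- cor.test(d$delta_measure, d$delta_dprime)
      tests[[length(tests) + 1L]] <- data.frame(
        family = "brain_behavior", measure = m, group = "all",
        statistic = unname(ct$statistic), df = unname(ct$parameter),
        estimate = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  if (!is.null(tests)) {
    tests$p_bonferroni <- NA_real_
    tests$p_BH <- NA_real_
    for (fam in unique(tests$family)) {
      idx <- tests$family == fam
      tests$p_bonferroni[idx] <- p.adjust(tests$p[idx], "bonferroni")
      tests$p_BH[idx] <- p.adjust(tests$p[idx], "BH")
    }
  }
  structure(list(tests = tests, cells = cells, from = from, to = to),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("Contrast report (", x$from, " -> ", x$to, "): ",
      if (is.null(x$tests)) 0L else nrow(x$tests), " tests\n", sep = "")
  if (!is.null(x$tests)) print.data.frame(x$tests, digits = 3)
  invisible(x)
}

# Stack static modularity + cartography into one long measure table:
# subject, group, session, measure, value.
long_measures <- function(modularity, cartography = NULL) {
  out <- data.frame(
    subject = modularity$subject, group = modularity$group,
    session = modularity$session,
    measure = paste0("Q_normalized|", modularity$condition),
    value = modularity$Q_normalized, stringsAsFactors = FALSE)
  if (!is.null(cartography)) {
    lab <- ifelse(cartography$measure == "recruitment",
                  paste0("recruitment|", cartography$system_k),
                  paste0("integration|", cartography$system_k, ":",
                         cartography$system_l))
    out <- rbind(out, data.frame(
      subject = cartography$subject, group = cartography$group,
      session = cartography$session, measure = lab,
      value = cartography$normalized, stringsAsFactors = FALSE))
  }
  out
}

measure_change <- function(measures, from, to) {
  before <- measures[measures$session == from, ]
  after <- measures[measures$session == to, ]
  merged <- merge(before, after, by = c("subject", "group", "measure"),
                  suffixes = c("_before", "_after"))
  data.frame(subject = merged$subject, group = merged$group,
             measure = merged$measure,
             delta = merged$value_after - merged$value_before,
             stringsAsFactors = FALSE)
}
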