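#' Configuration of the end-to-end analysis pipeline
#'
#' @param individuals individual table (data frame) or path to its CSV.
#' @param transects transect table (data frame) or path to its CSV.
#' @param seed global integer seed; every stochastic stage derives its own
#'   child seed from it, so stage results are reproducible independently
#'   of execution order.
#' @param n_boot bootstrap replicates for the FRic confidence intervals
#'   (default 10000, as in the field protocol the pipeline mirrors; lower
#'   it for quick runs).
#' @param n_boot_fove bootstrap replicates for the FOve intervals;
#'   defaults to `n_boot`.  Exact hull-intersection volumes cost far more
#'   than single-hull volumes, so a smaller replicate count is often the
#'   pragmatic choice here.
#' @param n_perm permutations for PERMANOVA and the RDA tests (default 999).
#' @param family count-model family, `"poisson"` or `"negbin"`.
#' @param avg_scope model-averaging scope (see [model_average()]).
#' @param cor_threshold collinearity screening threshold (default 0.9).
#' @param out_dir optional directory; when given, CSV tables and a JSON
#'   summary are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(individuals, transects, seed = 1,
                            n_boot = 10000, n_boot_fove = n_boot, n_perm = 999,
                            family = c("poisson", "negbin"),
                            avg_scope = c("all", "delta2", "cum95"),
                            cor_threshold = 0.9, out_dir = NULL) {
  family <- match.arg(family)
  avg_scope <- match.arg(avg_scope)
  if (n_boot < 1 || n_boot_fove < 1 || n_perm < 1) {
    stop("n_boot, n_boot_fove and n_perm must be positive")
  }
  if (is.character(individuals)) individuals <- read_individuals(individuals)
  if (is.character(transects)) transects <- read_transects(transects)
  structure(
    list(
      individuals = validate_individuals(individuals),
      transects = validate_transects(transects),
      seed = as.integer(seed), n_boot = as.integer(n_boot),
      n_boot_fove = as.integer(n_boot_fove),
      n_perm = as.integer(n_perm), family = family, avg_scope = avg_scope,
      cor_threshold = cor_threshold, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full intraspecific functional-niche analysis
#'
#' Chains the analysis stages in their canonical order: trait construction
#' and standardization; PCA functional space; niche metrics (FIde, FRic,
#' pairwise FOve, subsample bootstrap CIs at each distinct group size,
#' PERMANOVA); microhabitat screening (Shapiro-Wilk normality, then
#' collinearity); per-group all-subsets AICc GLMs with model averaging and
#' hierarchical partitioning; and the DCA-gated RDA of traits on
#' microhabitat variables with permutation tests.  Any stage failure is
#' re-signalled with the stage name attached.
#'
#' When the collinearity screen leaves more candidate predictors than the
#' transect sample can support (more than `n - 2`), the habitat-model
#' stage caps the per-group candidate set at the `n - 2` variables most
#' rank-associated with that group's counts, with a message; the full
#' model must remain estimable for AICc ranking and partitioning.
#'
#' @param config a [pipeline_config()] (or arguments forwarded to it).
#' @param ... forwarded to [pipeline_config()] when `config` is not
#'   already one.
#' @return a results bundle (list) with one element per stage:
#'   `traits`, `space`, `niche` (metrics + `bootstrap` table), `screening`,
#'   `habitat` (per group: model table summary, averaged coefficients,
#'   partition), `ordination` (`dca`, `rda`, `term_significance`) and
#'   `summary` (flat named list of headline numbers).  Written to
#'   `out_dir` as CSV/JSON when configured.
#' @export
run_pipeline <- function(config, ...) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(config, ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ind <- config$individuals
  env <- config$transects

  tm <- stage("traits", standardize_traits(compute_traits(ind)))
  space <- stage("functional_space", build_space(tm))

  niche <- stage("niche_metrics", {
    nm <- niche_metrics(space, n_perm = config$n_perm,
                        seed = child_seed(config$seed, "permanova"))
    sizes <- sort(unique(as.integer(table(space$meta$group))))
    by_group <- split_coords(space$coordinates, space$meta$group)
    v_pool <- hull_volume(space$coordinates)
    boots <- list()
    for (s in sizes) {
      el <- names(by_group)[vapply(by_group, nrow, integer(1)) > s]
      if (!length(el)) next
      fr <- bootstrap_metric(by_group, "fric", subsample_n = s,
                             n_reps = config$n_boot,
                             seed = child_seed(config$seed, paste0("boot_fric", s)),
                             pooled_volume = v_pool)
      fr$metric <- "fric"
      boots[[paste0("fric", s)]] <- fr
      if (length(el) >= 2) {
        fo <- bootstrap_metric(by_group, "fove", subsample_n = s,
                               n_reps = config$n_boot_fove,
                               seed = child_seed(config$seed, paste0("boot_fove", s)),
                               pooled_volume = v_pool)
        fo$metric <- "fove"
        boots[[paste0("fove", s)]] <- fo
      }
    }
    nm$bootstrap <- do.call(rbind, boots)
    rownames(nm$bootstrap) <- NULL
    nm
  })

  screening <- stage("screening", {
    ns <- normality_screen(env)
    cs <- correlation_screen(env, threshold = config$cor_threshold,
                             normality = ns)
    list(normality = ns, correlation = cs)
  })

  habitat <- stage("habitat_models", {
    kept <- screening$correlation$kept
    groups <- sub("^n_", "", grep("^n_", names(env), value = TRUE))
    out <- list()
    max_p <- nrow(env) - 2   # largest full model the sample can support
    for (g in groups) {
      counts <- env[[paste0("n_", g)]]
      kept_g <- kept
      if (length(kept_g) > max_p) {
        # keep the candidates most rank-associated with this group's counts
        assoc <- vapply(kept_g, function(v) {
          abs(suppressWarnings(cor(env[[v]], counts, method = "spearman")))
        }, numeric(1))
        kept_g <- kept_g[order(-assoc)][seq_len(max_p)]
        message("habitat_models (", g, "): candidate predictors capped at ",
                max_p, " (n - 2): ", paste(kept_g, collapse = ", "))
      }
      mt <- all_subsets(counts, env[, kept_g, drop = FALSE],
                        family = config$family)
      avg <- model_average(mt, scope = config$avg_scope)
      hp <- hierarchical_partition(counts, env[, kept_g, drop = FALSE],
                                   family = config$family)
      out[[g]] <- list(model_table = mt, averaged = avg, partition = hp)
    }
    out
  })

  ordn <- stage("ordination", {
    dca <- dca_gradient_length(tm$traits)
    kept <- screening$correlation$kept
    # environment values repeat within a transect, so the individual-level
    # matrix can have rank at most (number of occupied transects - 1)
    # after centring; cap the constraint set by marginal association with
    # the traits when the screen left more variables than that
    q_max <- length(unique(ind$transect)) - 1
    if (length(kept) > q_max) {
      y_c <- scale(tm$traits, center = TRUE, scale = FALSE)
      fmarg <- vapply(kept, function(v) {
        x1 <- scale(env[[v]][match(ind$transect, env$transect)])
        rda_pseudo_f(y_c, x1)
      }, numeric(1))
      kept <- kept[order(-fmarg)][seq_len(q_max)]
      message("ordination: RDA constraints capped at ", q_max,
              " (transects - 1): ", paste(kept, collapse = ", "))
    }
    env_ind <- env[match(ind$transect, env$transect), kept, drop = FALSE]
    rda <- rda_traits_env(tm$traits, env_ind, n_perm = config$n_perm,
                          seed = child_seed(config$seed, "rda"))
    ts <- rda_term_significance(tm$traits, env_ind, n_perm = config$n_perm,
                                seed = child_seed(config$seed, "rda_terms"))
    list(dca = dca, rda = rda, term_significance = ts)
  })

  summary <- pipeline_summary(space, niche, habitat, ordn)
  bundle <- list(
    traits = tm, space = space, niche = niche, screening = screening,
    habitat = habitat, ordination = ordn, summary = summary,
    config = config[c("seed", "n_boot", "n_perm", "family", "avg_scope",
                      "cor_threshold")]
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

pipeline_summary <- function(space, niche, habitat, ordn) {
  s <- list(
    n_individuals = nrow(space$coordinates),
    retained_axes = space$retained_axes,
    explained_pct_retained = sum(space$explained_pct[seq_len(space$retained_axes)]),
    permanova_pseudo_F = niche$permanova$pseudo_F,
    permanova_p = niche$permanova$p,
    dca_axis1_length = ordn$dca$axis1_gradient_length,
    dca_recommendation = ordn$dca$recommendation,
    rda_first_two_axes_pct = sum(ordn$rda$pct_of_total[seq_len(min(2, length(ordn$rda$pct_of_total)))]),
    rda_perm_F = ordn$rda$perm_test$F,
    rda_perm_p = ordn$rda$perm_test$p
  )
  for (g in names(niche$fric)) s[[paste0("fric_", g)]] <- unname(niche$fric[g])
  for (i in seq_len(nrow(niche$fove))) {
    s[[paste0("fove_", niche$fove$group_a[i], "_", niche$fove$group_b[i])]] <-
      niche$fove$fove[i]
  }
  for (g in names(habitat)) {
    hp <- habitat[[g]]$partition
    top <- hp$predictor[which.max(hp$I_pct)]
    s[[paste0("hp_top_", g)]] <- top
    s[[paste0("hp_top_pct_", g)]] <- max(hp$I_pct)
  }
  s
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) write.csv(x, file.path(out_dir, f), row.names = FALSE)
  w(as.data.frame(bundle$traits), "traits.csv")
  w(data.frame(id = rownames(bundle$space$coordinates),
               bundle$space$coordinates), "coordinates.csv")
  w(data.frame(trait = rownames(bundle$space$loadings),
               bundle$space$loadings), "loadings.csv")
  w(bundle$niche$fove, "fove.csv")
  if (!is.null(bundle$niche$bootstrap)) w(bundle$niche$bootstrap, "bootstrap.csv")
  for (g in names(bundle$habitat)) {
    w(bundle$habitat[[g]]$model_table$table, paste0("models_", g, ".csv"))
    w(bundle$habitat[[g]]$averaged, paste0("averaged_", g, ".csv"))
    w(as.data.frame(bundle$habitat[[g]]$partition), paste0("partition_", g, ".csv"))
  }
  jsonlite::write_json(
    bundle$summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
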