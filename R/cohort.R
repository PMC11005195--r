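# Stable per-entity seed derivation: one user-facing seed fans out to child
# seeds so adding an embryo or a stage never perturbs earlier draws.
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Cohort configuration
#'
#' Describes a multi-group imaging experiment: group sizes, per-domain
#' activity multipliers, the gain-of-function genotype effect, the
#' MEK-inhibitor dose response and the detector noise, all driven by one seed.
#'
#' @param groups List of groups, each a list with `name`, `n_embryos` (>= 1)
#'   and `multipliers` (named numeric, per-domain activity multipliers;
#'   domains missing from the list keep multiplier 1).
#' @param base_activities Named baseline activities per domain (wild-type
#'   embryo), default `c(margin = 0.2, bulk = 0.1)`.
#' @param stage Phantom stage for the cohort, default `"gastrula_5hpf"`.
#' @param shape Image size `c(ny, nx)`, default 128 x 128.
#' @param embryo_sdlog Between-embryo lognormal variability (sd of log
#'   multiplier), default 0.1.
#' @param noise A [noise_model()].
#' @param morphology Optional list mapping group name to a list with
#'   `axis_ratio` and `body_length_px` truth values (plus optional
#'   `ratio_sdlog`, default 0.02); enables per-embryo morphology masks.
#' @param acquisition A [spectral_acquisition()].
#' @param bleach List with `iterations` and `per_iteration_survival` for the
#'   AB-FRET series.
#' @param seed Integer master seed; identical configs and seeds reproduce the
#'   cohort bit for bit.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(groups,
                          base_activities = c(margin = 0.2, bulk = 0.1),
                          stage = "gastrula_5hpf", shape = c(128L, 128L),
                          embryo_sdlog = 0.1, noise = noise_model(),
                          morphology = NULL,
                          acquisition = spectral_acquisition(),
                          bleach = list(iterations = 50L,
                                        per_iteration_survival = 0.85),
                          seed = 1L) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("`groups` must be a non-empty list", call. = FALSE)
  for (g in groups) {
    if (is.null(g$name) || is.null(g$n_embryos) || g$n_embryos < 1)
      stop("each group needs `name` and `n_embryos` >= 1", call. = FALSE)
  }
  structure(list(groups = groups, base_activities = base_activities,
                 stage = stage, shape = as.integer(shape),
                 embryo_sdlog = embryo_sdlog, noise = noise,
                 morphology = morphology, acquisition = acquisition,
                 bleach = bleach, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default four-group Noonan-syndrome scenario
#'
#' The study conditions used throughout: wild-type Shp2 (`Shp2WT`),
#' gain-of-function mutant (`Shp2D61G`, margin activity multiplier 3),
#' and the mutant under low- (0.25 uM, suppression 0.7) and high-dose
#' (1 uM, suppression 0.4) MEK inhibitor. Morphology truth encodes the rescue
#' logic: the mutant's elevated axis ratio and shortened body are partially
#' restored at low dose and fully restored at high dose.
#'
#' @param n_embryos Embryos per group, default 8.
#' @param seed Master seed.
#' @param genotype_effect Margin-activity multiplier of the mutant, default 4.
#'   The default keeps the rescued high-dose group above wild type (partial
#'   molecular rescue) with group separations well clear of the between-embryo
#'   variability.
#' @param dose_response Named suppression factors in (0, 1] applied on top of
#'   the genotype effect; default `c("0.25" = 0.7, "1" = 0.4)` (uM doses).
#' @param ... Passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
noonan_cohort_config <- function(n_embryos = 8L, seed = 1L,
                                 genotype_effect = 4,
                                 dose_response = c("0.25" = 0.7, "1" = 0.4),
                                 ...) {
  if (any(diff(dose_response[order(as.numeric(names(dose_response)))]) > 0))
    stop("`dose_response` suppression must decrease with dose", call. = FALSE)
  gmul <- function(m) list(margin = m)
  groups <- list(
    list(name = "Shp2WT", n_embryos = n_embryos, multipliers = gmul(1)),
    list(name = "Shp2D61G", n_embryos = n_embryos,
         multipliers = gmul(genotype_effect)),
    list(name = "Shp2D61G_PD0.25uM", n_embryos = n_embryos,
         multipliers = gmul(genotype_effect * dose_response[["0.25"]])),
    list(name = "Shp2D61G_PD1uM", n_embryos = n_embryos,
         multipliers = gmul(genotype_effect * dose_response[["1"]])))
  morphology <- list(
    Shp2WT = list(axis_ratio = 1.30, body_length_px = 110),
    Shp2D61G = list(axis_ratio = 1.60, body_length_px = 88),
    Shp2D61G_PD0.25uM = list(axis_ratio = 1.45, body_length_px = 99),
    Shp2D61G_PD1uM = list(axis_ratio = 1.30, body_length_px = 107))
  cohort_config(groups = groups, morphology = morphology, seed = seed, ...)
}

#' Generate a cohort of rendered embryos
#'
#' For every embryo: draws a per-embryo lognormal multiplier, builds the
#' activity phantom, and (optionally) renders the lambda stack, the
#' acceptor-photobleaching series at the margin, and a morphology mask.
#' Everything is reproducible from the config seed.
#'
#' @param config A [cohort_config()].
#' @param render Character subset of `c("lambda", "bleach", "morphology")`
#'   selecting which data to render per embryo (truth phantoms are always
#'   produced).
#' @return List of class `cohort` with `embryos` (each a list with
#'   `embryo_id`, `group`, `phantom`, and any of `lambda`, `bleach`,
#'   `morphology`), `truth` (per-embryo data.frame of ground-truth margin
#'   activity/efficiency and morphology) and `config`.
#' @export
make_cohort <- function(config,
                        render = c("lambda", "bleach", "morphology")) {
  stopifnot(inherits(config, "cohort_config"))
  bad <- setdiff(render, c("lambda", "bleach", "morphology"))
  if (length(bad))
    stop(sprintf("unknown render option(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  embryos <- list(); truth <- list()
  for (g in config$groups) {
    for (i in seq_len(g$n_embryos)) {
      id <- sprintf("%s_%02d", g$name, i)
      eseed <- derive_seed(config$seed, id)
      set.seed(eseed)
      jitter <- exp(stats::rnorm(1, 0, config$embryo_sdlog))
      acts <- config$base_activities
      for (dom in names(g$multipliers))
        acts[dom] <- acts[dom] * g$multipliers[[dom]]
      acts <- pmin(pmax(acts * jitter, 0), 1)
      phantom <- make_embryo_phantom(config$stage, config$shape,
                                     domain_activities = acts,
                                     seed = derive_seed(eseed, "phantom"))
      target_dom <- if (any(phantom$labels == "margin")) "margin" else "tailbud"
      emb <- list(embryo_id = id, group = g$name, phantom = phantom,
                  target_domain = target_dom)
      if ("lambda" %in% render)
        emb$lambda <- render_lambda_stack(phantom,
                                          acquisition = config$acquisition,
                                          noise = config$noise,
                                          seed = derive_seed(eseed, "lambda"))
      if ("bleach" %in% render)
        emb$bleach <- render_bleach_series(
          phantom, roi_from_domain(phantom, target_dom),
          iterations = config$bleach$iterations,
          per_iteration_survival = config$bleach$per_iteration_survival,
          noise = config$noise, seed = derive_seed(eseed, "bleach"))
      morpho_truth <- list(axis_ratio = NA_real_, body_length_px = NA_real_)
      if ("morphology" %in% render && !is.null(config$morphology)) {
        mt <- config$morphology[[g$name]]
        if (is.null(mt))
          stop(sprintf("no morphology truth for group '%s'", g$name), call. = FALSE)
        sdl <- if (is.null(mt$ratio_sdlog)) 0.02 else mt$ratio_sdlog
        set.seed(derive_seed(eseed, "morpho"))
        ratio <- mt$axis_ratio * exp(stats::rnorm(1, 0, sdl))
        minor <- 0.32 * min(config$shape) * 2
        shape_m <- as.integer(config$shape * 2L)
        emb$morphology <- list(
          oval_mask = make_morphology_phantom(ratio * minor, minor,
                                              rotation_deg = stats::runif(1, 0, 180),
                                              shape = shape_m),
          body_length_px = mt$body_length_px * exp(stats::rnorm(1, 0, sdl)))
        morpho_truth <- list(axis_ratio = ratio,
                             body_length_px = emb$morphology$body_length_px)
      }
      margin <- phantom$labels == target_dom
      truth[[id]] <- data.frame(
        embryo_id = id, group = g$name,
        margin_activity = mean(phantom$activity[margin]),
        margin_efficiency = mean(phantom$efficiency[margin]),
        axis_ratio = morpho_truth$axis_ratio,
        body_length_px = morpho_truth$body_length_px,
        stringsAsFactors = FALSE)
      embryos[[id]] <- emb
    }
  }
  structure(list(embryos = embryos,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x$embryos, `[[`, character(1), "group"))
  cat(sprintf("<cohort> %d embryos in %d groups (%s), stage %s, seed %d\n",
              length(x$embryos), length(tab),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = "; "),
              x$config$stage, x$config$seed))
  invisible(x)
}
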