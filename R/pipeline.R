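# Scenario pipeline: the computational stages of the denture design
# algorithm. Clinical stages (impressions, occlusal registration, try-in,
# manufacturing) are carried as named no-op log entries so the stage
# sequence stays faithful to the clinical workflow without pretending to
# implement it.

PIPELINE_STAGES <- c(
  "impressions (clinical, no-op)",
  "occlusal registration (clinical, no-op)",
  "geometry generation",
  "foundation calibration",
  "static FEM solves",
  "fatigue-life mapping",
  "variant comparison / report",
  "try-in and manufacturing (clinical, no-op)")

#' Canonical per-block load cases
#'
#' Blocks I-IV, each under symmetric (two-sided) and asymmetric
#' (right-side) loading at the same total force.
#'
#' @param F0 total force per case, N.
#' @return named list of [load_case()] objects (`I_sym`, `I_asym`, ...).
#' @export
canonical_cases <- function(F0 = 100) {
  out <- list()
  for (b in BLOCKS) {
    out[[paste0(b, "_sym")]] <- load_case(b, "symmetric", F0)
    out[[paste0(b, "_asym")]] <- load_case(b, "asymmetric-right", F0)
  }
  out
}

#' Standard tooth-arrangement variants
#'
#' `normal` (zero spec), `displaced` (anterior blocks shifted 2 mm
#' vestibularly) and `inclined` (anterior blocks tilted 15 degrees).
#' Magnitudes are package defaults for demonstration; both are well inside
#' the arrangement limits.
#'
#' @return named list of [arrangement_spec()] objects.
#' @export
arrangement_variants <- function() {
  list(normal = arrangement_spec(),
       displaced = arrangement_spec(disp_vo = c(I = 2, II = 2)),
       inclined = arrangement_spec(incl_deg = c(I = 15, II = 15)))
}

#' Analysis scenario
#'
#' Bundles everything needed for a reproducible run: geometry and
#' arrangement, materials, fatigue constants, foundation spec (optionally
#' recalibrated), the load cases, fatigue criterion and seed.
#'
#' @param name scenario label.
#' @param params [arch_parameters()].
#' @param arrangement [arrangement_spec()].
#' @param materials [material_set()].
#' @param fatigue [fatigue_params()].
#' @param foundation [foundation_spec()].
#' @param calibrate if `TRUE` (default) calibrate the foundation against
#'   the uniform all-teeth case before the load cases are run.
#' @param cases named list of [load_case()] objects.
#' @param criterion,cycle_model passed to [life_field()].
#' @param seed integer seed recorded with all outputs.
#' @return an object of class `scenario`.
#' @export
scenario <- function(name = "normal", params = arch_parameters(),
                     arrangement = arrangement_spec(),
                     materials = material_set(),
                     fatigue = fatigue_params(),
                     foundation = foundation_spec(),
                     calibrate = TRUE, cases = canonical_cases(),
                     criterion = "swt-principal",
                     cycle_model = "pulsating", seed = 1L) {
  stopifnot(inherits(params, "arch_parameters"),
            inherits(arrangement, "arrangement_spec"),
            inherits(materials, "material_set"),
            inherits(fatigue, "fatigue_params"),
            inherits(foundation, "foundation_spec"),
            length(cases) >= 1)
  structure(list(name = name, params = params, arrangement = arrangement,
                 materials = materials, fatigue = fatigue,
                 foundation = foundation, calibrate = isTRUE(calibrate),
                 cases = cases, criterion = criterion,
                 cycle_model = cycle_model, seed = as.integer(seed)),
            class = "scenario")
}

#' Configuration hash of any serializable object
#'
#' MD5 of the canonical serialization; recorded in every report so outputs
#' can be traced to their exact configuration.
#'
#' @param x an R object (typically a [scenario()]).
#' @return hex digest string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

# patch label nearest to a node (patch of any boundary facet containing
# it, else the patch of the geometrically closest labeled facet centroid)
node_patch <- function(mesh, node) {
  hit <- which(rowSums(mesh$facets == node) > 0)
  if (length(hit)) {
    tab <- sort(table(mesh$facet_patch[hit]), decreasing = TRUE)
    return(names(tab)[1])
  }
  g <- facet_geometry(mesh$nodes, mesh$facets)
  d2 <- rowSums(sweep(g$centroid, 2, mesh$nodes[node, ])^2)
  mesh$facet_patch[which.min(d2)]
}

#' Run a scenario
#'
#' Executes the computational pipeline: generate the geometry, calibrate
#' the foundation (optional), assemble and factor the system once, then
#' for every load case solve, check equilibrium, recover stresses and map
#' the fatigue-life field. Deterministic for a fixed scenario and seed.
#'
#' @param sc a [scenario()].
#' @param verbose log stage messages.
#' @return a `scenario_result`: list with `mesh`, `foundation`, per-case
#'   `cases` (displacements, stress and life fields, metrics), a `summary`
#'   data.frame, the stage `log` and the scenario `hash`.
#' @export
run_scenario <- function(sc, verbose = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  hash <- config_hash(sc)
  say("scenario '%s' (config %s)", sc$name, hash)
  for (st in PIPELINE_STAGES[1:2]) say("stage: %s", st)

  say("stage: geometry generation (arrangement: %s)",
      if (is_zero_arrangement(sc$arrangement)) "normal" else "modified")
  mesh <- generate_denture(sc$params, sc$arrangement, sc$seed)

  fnd <- sc$foundation
  if (sc$calibrate) {
    say("stage: foundation calibration")
    fnd <- tryCatch(
      calibrate_foundation(mesh, sc$materials, fnd),
      error = function(e) stop("pipeline stage 'foundation calibration' ",
                               "failed: ", conditionMessage(e)))
  }
  say("stage: static FEM solves (%d cases)", length(sc$cases))
  system <- assemble_system(mesh, sc$materials, fnd)
  fct <- factor_system(system)

  results <- list()
  rows <- list()
  for (nm in names(sc$cases)) {
    cs <- sc$cases[[nm]]
    f <- build_load_case(cs, mesh)
    u <- solve_factored(fct, system, f)
    reac <- reaction_sum(u, system)
    applied <- attr(f, "total_force")
    imb <- abs(reac[["Fz"]] + applied[["Fz"]]) / abs(applied[["Fz"]])
    if (imb > 1e-3)
      stop("pipeline stage 'static FEM solves' failed: equilibrium ",
           sprintf("violated for case %s (imbalance %.3g)", nm, imb))
    stress <- recover_stress(u, mesh, sc$materials)
    life <- life_field(stress, sc$fatigue, criterion = sc$criterion,
                       cycle_model = sc$cycle_model)
    rmm <- rigid_motion_metrics(u, mesh)
    imax <- which.max(stress$nodal$von_mises)
    zones <- hazard_zones(mesh, life)
    results[[nm]] <- list(case = cs, u = u, stress = stress, life = life,
                          metrics = rmm, reactions = reac)
    rows[[nm]] <- data.frame(
      case = nm, blocks = paste(cs$blocks, collapse = "+"),
      sidedness = cs$sidedness, F0 = cs$F0,
      pressure = attr(f, "pressure"),
      max_raw_mises = stress$max_raw_mises,
      max_nodal_mises = stress$max_nodal_mises,
      max_location = node_patch(mesh, imax),
      min_N = min(life$N), min_years = min(life$years),
      red_fraction = mean(life$hazard == "red"),
      hazard_zones = zones,
      stringsAsFactors = FALSE)
  }
  say("stage: fatigue-life mapping (criterion %s, %s cycles)",
      sc$criterion, sc$cycle_model)
  for (st in PIPELINE_STAGES[7:8]) say("stage: %s", st)
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(scenario = sc, mesh = mesh, foundation = fnd,
                 cases = results, summary = summary, log = log,
                 hash = hash),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s' (%d cases, config %s)\n",
              x$scenario$name, length(x$cases), substr(x$hash, 1, 8)))
  print(x$summary[, c("case", "max_nodal_mises", "min_N", "min_years",
                      "red_fraction")])
  invisible(x)
}

#' Compare tooth-arrangement scenarios
#'
#' Runs (or reuses) the given scenarios, checks they are comparable (same
#' mesh resolution, element order and load cases), ranks the variants by
#' minimum predicted life and reports stress/life ratios relative to the
#' first (reference) scenario, plus hazard-zone counts for multi-zone
#' localization.
#'
#' @param scenarios named list of [scenario()] objects or
#'   `scenario_result`s (first entry = reference, typically the normal
#'   arrangement).
#' @param verbose passed to [run_scenario()].
#' @return a `comparison_report`: list with `per_scenario` summary,
#'   `ranking`, and the per-case `ratios` table.
#' @export
compare_arrangements <- function(scenarios, verbose = FALSE) {
  stopifnot(length(scenarios) >= 2, !is.null(names(scenarios)))
  key <- function(s) {
    sc <- if (inherits(s, "scenario_result")) s$scenario else s
    list(ms = sc$params$mesh_size, ord = sc$params$element_order,
         cases = names(sc$cases))
  }
  k0 <- key(scenarios[[1]])
  for (s in scenarios[-1])
    if (!identical(k0, key(s)))
      stop("scenarios are not comparable (mesh resolution, element order ",
           "and load cases must match)")
  results <- lapply(scenarios, function(s) {
    if (inherits(s, "scenario_result")) s else run_scenario(s, verbose)
  })
  ref <- results[[1]]
  per <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    data.frame(scenario = nm,
               worst_case = s$case[which.min(s$min_N)],
               min_N = min(s$min_N), min_years = min(s$min_years),
               max_stress = max(s$max_nodal_mises),
               max_hazard_zones = max(s$hazard_zones),
               stringsAsFactors = FALSE)
  }))
  per$life_ratio_vs_ref <- per$min_N / per$min_N[1]
  ranking <- per$scenario[order(per$min_N, decreasing = TRUE)]
  ratios <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    data.frame(scenario = nm, case = s$case,
               stress_ratio = s$max_nodal_mises /
                 ref$summary$max_nodal_mises,
               life_ratio = s$min_N / ref$summary$min_N,
               hazard_zones = s$hazard_zones,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_scenario = per, ranking = ranking, ratios = ratios,
                 results = results),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ranking (best service life first):",
      paste(x$ranking, collapse = " > "), "\n")
  print(x$per_scenario)
  invisible(x)
}

#' Render pipeline results to files
#'
#' Writes, per load case, a VTK file with displacement, von Mises (raw and
#' normalized to its maximum, with 10 percent isoline levels as metadata),
#' first principal stress, log10 cycles-to-failure and years fields; a CSV
#' max-stress table (blocks x symmetric/asymmetric); and a JSON summary
#' recording every assumption (fatigue constants and their placeholder
#' status, mastication schedule, criterion, seed and config hash). An
#' empty result produces a valid empty report with a warning.
#'
#' @param result a `scenario_result` or `comparison_report`.
#' @param dir output directory (created if missing).
#' @return invisibly the vector of files written.
#' @export
render_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(result, "comparison_report")) {
    for (nm in names(result$results))
      files <- c(files, render_report(result$results[[nm]],
                                      file.path(dir, nm)))
    cmp <- file.path(dir, "comparison.csv")
    write.csv(result$ratios, cmp, row.names = FALSE)
    jj <- file.path(dir, "comparison.json")
    jsonlite::write_json(list(ranking = result$ranking,
                              per_scenario = result$per_scenario),
                         jj, auto_unbox = TRUE, digits = NA)
    return(invisible(c(files, cmp, jj)))
  }
  if (!inherits(result, "scenario_result") || !length(result$cases)) {
    warning("empty results: writing empty report")
    jj <- file.path(dir, "summary.json")
    jsonlite::write_json(list(cases = list()), jj, auto_unbox = TRUE)
    return(invisible(jj))
  }
  for (nm in names(result$cases)) {
    cs <- result$cases[[nm]]
    vm <- cs$stress$nodal$von_mises
    fp <- file.path(dir, paste0("case_", nm, ".vtk"))
    write_vtk_fields(result$mesh, fp, point_data = list(
      displacement = unclass(cs$u)[, , drop = FALSE],
      von_mises = vm,
      von_mises_normalized = vm / max(vm, .Machine$double.eps),
      sigma1 = cs$stress$nodal$s1,
      log10_cycles = log10(cs$life$N),
      years = cs$life$years))
    files <- c(files, fp)
  }
  # Table-2-style layout: blocks x loading mode, max nodal von Mises
  s <- result$summary
  bl <- sub("_(sym|asym)$", "", s$case)
  md <- ifelse(grepl("_sym$", s$case), "symmetric", "asymmetric")
  if (all(bl %in% BLOCKS)) {
    tab <- tapply(s$max_nodal_mises, list(md, bl), max)
    tab <- tab[intersect(c("symmetric", "asymmetric"), rownames(tab)),
               intersect(BLOCKS, colnames(tab)), drop = FALSE]
    tf <- file.path(dir, "max_stress_table.csv")
    write.csv(as.data.frame(tab), tf)
    files <- c(files, tf)
  }
  sf <- file.path(dir, "summary.csv")
  write.csv(s, sf, row.names = FALSE)
  jj <- file.path(dir, "summary.json")
  fat <- result$scenario$fatigue
  jsonlite::write_json(list(
    scenario = result$scenario$name,
    config_hash = result$hash,
    seed = result$scenario$seed,
    criterion = result$scenario$criterion,
    cycle_model = result$scenario$cycle_model,
    assumptions = list(
      fatigue_constants = fat[c("sigma_02", "sigma_f", "beta", "sigma_L",
                                "swt_sigma_u", "swt_sigma_V", "swt_beta")],
      fatigue_constants_placeholder = fat$placeholder,
      schedule = list(meals_per_day = fat$meals_per_day,
                      chews_per_meal = fat$chews_per_meal),
      contour_levels = seq(0.1, 1, 0.1)),
    summary = s,
    log = result$log),
    jj, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sf, jj))
}

# ---- YAML scenario configs -------------------------------------------------

#' Write a scenario to a YAML config
#' @param sc a [scenario()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  pa <- unclass(sc$params)
  pa$block_footprints <- as.list(pa$block_footprints)
  lst <- list(
    name = sc$name,
    params = pa,
    arrangement = list(disp_vo = as.list(sc$arrangement$disp_vo),
                       disp_ap = as.list(sc$arrangement$disp_ap),
                       incl_deg = as.list(sc$arrangement$incl_deg),
                       side = sc$arrangement$side),
    materials = list(E = as.list(sc$materials$E),
                     nu = as.list(sc$materials$nu),
                     rho = as.list(sc$materials$rho),
                     sigma_uc = sc$materials$sigma_uc),
    fatigue = unclass(sc$fatigue)[c("sigma_02", "sigma_f", "beta",
                                    "swt_sigma_u", "swt_sigma_V", "swt_beta",
                                    "n_max", "meals_per_day",
                                    "chews_per_meal")],
    foundation = list(k_segments = as.list(sc$foundation$k_segments),
                      k_seal = sc$foundation$k_seal,
                      k_retention = sc$foundation$k_retention,
                      c1 = sc$foundation$c1),
    calibrate = sc$calibrate,
    cases = lapply(sc$cases, function(cs)
      list(blocks = cs$blocks, sidedness = cs$sidedness, F0 = cs$F0)),
    criterion = sc$criterion, cycle_model = sc$cycle_model, seed = sc$seed)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' Read a scenario from a YAML config
#' @param path YAML file written by [write_scenario()] (or hand-edited).
#' @return a [scenario()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  pa <- y$params
  pa$block_footprints <- unlist(pa$block_footprints)
  pa$retention_ellipse_axes <- unlist(pa$retention_ellipse_axes)
  params <- do.call(arch_parameters, pa)
  arr <- arrangement_spec(disp_vo = unlist(y$arrangement$disp_vo),
                          disp_ap = unlist(y$arrangement$disp_ap),
                          incl_deg = unlist(y$arrangement$incl_deg),
                          side = y$arrangement$side %||% "both")
  mats <- material_set(E = unlist(y$materials$E),
                       nu = unlist(y$materials$nu),
                       rho = unlist(y$materials$rho),
                       sigma_uc = y$materials$sigma_uc)
  fat <- do.call(fatigue_params, c(y$fatigue, list(confirmed = TRUE)))
  fnd <- foundation_spec(k_segments = unlist(y$foundation$k_segments),
                         k_seal = y$foundation$k_seal,
                         k_retention = y$foundation$k_retention,
                         c1 = y$foundation$c1 %||% 0)
  cases <- lapply(y$cases, function(cs)
    load_case(unlist(cs$blocks), cs$sidedness, cs$F0))
  scenario(name = y$name %||% "scenario", params = params,
           arrangement = arr, materials = mats, fatigue = fat,
           foundation = fnd, calibrate = isTRUE(y$calibrate),
           cases = cases, criterion = y$criterion %||% "swt-principal",
           cycle_model = y$cycle_model %||% "pulsating",
           seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
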