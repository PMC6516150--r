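## End-to-end orchestration: raw tables/images -> per-animal metrics ->
## Grubbs exclusion -> group statistics -> CSV report + JSON manifest.
## Per-animal computations never see group labels (blinded stages);
## labels enter only at the comparison step.

#' Generate a complete demo input bundle
#'
#' Writes synthetic wire, pressure, MRI and PWV CSV files, elastin
#' fiber TIFF images, and a matching YAML run configuration into `dir`.
#' Two groups are simulated: a compliant control and a stiff phenotype
#' (higher beta, steeper diameter-tension slope, smaller diameters,
#' straighter elastin). Fully deterministic given `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param nPerGroup animals per group.
#' @return path to the written config YAML.
#' @export
makeDemoInputs <- function(dir, seed = 1L, nPerGroup = 4L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  grp <- c("control", "stiff")
  ## wire: stiff = steeper slope, smaller y0
  wire <- do.call(rbind, lapply(seq_len(2L * nPerGroup), function(i) {
    g <- grp[(i - 1L) %/% nPerGroup + 1L]
    slope <- if (g == "control") 0.010 else 0.016
    y0 <- if (g == "control") 850 else 760
    cv <- makeWireCurve(slope, y0, nSteps = 10L, noiseSd = 0.05,
                        seed = seed + i,
                        segmentId = sprintf("%s_%02d", g, i))
    data.frame(segment_id = cv@segmentId, segment_length_mm = 2,
               step = seq_along(cv@diameter), diameter_um = cv@diameter,
               tension_mN_per_mm = cv@tension, group = g)
  }))
  utils::write.csv(wire, file.path(dir, "wire.csv"), row.names = FALSE)
  ## pressure: stiff = higher beta, smaller D00
  press <- do.call(rbind, lapply(seq_len(2L * nPerGroup), function(i) {
    g <- grp[(i - 1L) %/% nPerGroup + 1L]
    vm <- vesselModel(D00 = if (g == "control") 210 else 180,
                      beta = if (g == "control") 4 else 7,
                      wallCsa = 1.8e4, noiseSd = 1, seed = seed + 100L + i)
    ps <- makePressureSeries(vm, animalId = sprintf("%s_%02d", g, i))
    data.frame(animal_id = ps@animalId, pressure_mmHg = ps@pressure,
               di_um = ps@innerDiameter, de_um = ps@outerDiameter,
               group = g)
  }))
  utils::write.csv(press, file.path(dir, "pressure.csv"),
                   row.names = FALSE)
  ## MRI: stiff = shallower ascending slope
  mri <- do.call(rbind, lapply(seq_len(2L * nPerGroup), function(i) {
    g <- grp[(i - 1L) %/% nPerGroup + 1L]
    cv <- makeAreaWaveform(aDia = if (g == "control") 1.0 else 0.8,
                           aSys = if (g == "control") 1.25 else 0.9,
                           riseMs = 20, noiseSd = 0.01,
                           seed = seed + 200L + i,
                           animalId = sprintf("%s_%02d", g, i))
    data.frame(animal_id = cv@animalId, slice_id = "upper",
               time_ms = cv@time, area_mm2 = cv@area,
               heart_period_ms = cv@heartPeriod, group = g)
  }))
  utils::write.csv(mri, file.path(dir, "mri.csv"), row.names = FALSE)
  ## PWV: stiff = shorter transit time
  pwv <- do.call(rbind, lapply(seq_len(2L * nPerGroup), function(i) {
    g <- grp[(i - 1L) %/% nPerGroup + 1L]
    tt <- withSeed(seed + 300L + i,
                   stats::rnorm(1, if (g == "control") 10 else 7, 0.4))
    data.frame(animal_id = sprintf("%s_%02d", g, i), distance_mm = 40,
               t_aorta_ms = 2, t_femoral_ms = 2 + tt, group = g)
  }))
  utils::write.csv(pwv, file.path(dir, "pwv.csv"), row.names = FALSE)
  ## elastin: stiff = straighter fibers (smaller amplitude)
  imgdir <- file.path(dir, "elastin")
  dir.create(imgdir, showWarnings = FALSE)
  elrows <- do.call(rbind, lapply(seq_len(2L * nPerGroup), function(i) {
    g <- grp[(i - 1L) %/% nPerGroup + 1L]
    amp <- if (g == "control") 9 else 4
    fi <- makeFiberImage(fiberSpec(amplitude = amp, wavelength = 60,
                                   nFibers = 4L,
                                   imageShape = c(220L, 150L),
                                   snr = 8, seed = seed + 400L + i))
    f <- file.path(imgdir, sprintf("%s_%02d.tif", g, i))
    writeGrayTiff(fi$image, f, scale = max(fi$image))
    data.frame(animal_id = sprintf("%s_%02d", g, i), path = f,
               pixel_size_um = 1, group = g)
  }))
  utils::write.csv(elrows, file.path(dir, "elastin.csv"),
                   row.names = FALSE)
  cfg <- list(
    seed = seed,
    inputs = list(wire = file.path(dir, "wire.csv"),
                  pressure = file.path(dir, "pressure.csv"),
                  mri = file.path(dir, "mri.csv"),
                  pwv = file.path(dir, "pwv.csv"),
                  elastin = file.path(dir, "elastin.csv")),
    groups = list(column = "group", control = "control"),
    parameters = list(alpha = 0.05, qc_threshold = 5,
                      median_radius_px = 2, ball_radius_px = 20,
                      min_component_px = 64, isobar_mmHg = 100),
    output_dir = file.path(dir, "out"))
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  cfgPath
}

.checkInputs <- function(cfg) {
  for (nm in names(cfg$inputs)) {
    p <- cfg$inputs[[nm]]
    if (!file.exists(p))
      stop("config validation: input file for '", nm,
           "' does not exist: ", p)
  }
}

.writeCsvStable <- function(df, path) {
  ## fixed 15-significant-digit formatting keeps reruns byte-identical
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Reads the YAML run configuration (or an equivalent list), computes
#' per-animal metrics for every supplied modality, applies per-group
#' Grubbs outlier exclusion, compares groups, and writes one CSV per
#' modality plus `group_comparisons.csv` and a JSON manifest recording
#' seed, parameters and every exclusion with its reason. Re-running
#' with the same config reproduces byte-identical metric CSVs.
#'
#' @param config path to a YAML file or a config list.
#' @return (invisibly) a list with the metric tables, comparisons and
#'   the manifest.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .checkInputs(cfg)
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pars <- cfg$parameters
  alpha <- pars$alpha %||% 0.05
  groupCol <- cfg$groups$column %||% "group"
  exclusions <- list()
  noteExcl <- function(stage, id, reason) {
    exclusions[[length(exclusions) + 1L]] <<-
      list(stage = stage, id = id, reason = reason)
  }
  metrics <- list()   # per-animal long table: animal, group, metric, value

  ## ---- wire ----
  if (!is.null(cfg$inputs$wire)) {
    curves <- readWireCSV(cfg$inputs$wire)
    rows <- lapply(curves, function(cv) {
      fit <- tryCatch(analyzeWireCurve(cv, pars$isobar_mmHg %||% 100),
                      error = function(e)
                        stop("wire stage failed on segment '",
                             cv@segmentId, "': ", conditionMessage(e)))
      data.frame(segment_id = cv@segmentId, slope = fit@slope,
                 intercept = fit@intercept, y0_um = fit@y0Diameter,
                 d100_um = fit@d100, r2 = fit@r2,
                 qc_keep = fit@defined,
                 group = cv@metadata[[groupCol]] %||% NA_character_)
    })
    wireTab <- do.call(rbind, rows)
    .writeCsvStable(wireTab, file.path(outdir, "wire_fits.csv"))
    for (m in c("slope", "y0_um", "d100_um"))
      metrics[[paste0("wire_", m)]] <-
        data.frame(id = wireTab$segment_id, group = wireTab$group,
                   value = wireTab[[m]])
  }

  ## ---- pressure ----
  if (!is.null(cfg$inputs$pressure)) {
    series <- readPressureCSV(cfg$inputs$pressure)
    mech <- lapply(series, function(s)
      tryCatch(passiveMechanics(s), error = function(e)
        stop("pressure stage failed on animal '", s@animalId, "': ",
             conditionMessage(e))))
    perP <- do.call(rbind, lapply(seq_along(series), function(i) {
      s <- series[[i]]; m <- mech[[i]]
      data.frame(animal_id = s@animalId, pressure_mmHg = m@pressure,
                 di_um = s@innerDiameter, de_um = s@outerDiameter,
                 wt_um = m@wallThickness, wall_lumen = m@wallToLumen,
                 strain = m@strain, stress_dyn_cm2 = m@stress,
                 group = s@metadata[[groupCol]] %||% NA_character_)
    }))
    .writeCsvStable(perP, file.path(outdir, "pressure_mechanics.csv"))
    betaTab <- do.call(rbind, lapply(seq_along(series), function(i)
      data.frame(animal_id = series[[i]]@animalId,
                 beta = mech[[i]]@beta,
                 sigma_orig = mech[[i]]@sigmaOrig, r2 = mech[[i]]@r2,
                 group = series[[i]]@metadata[[groupCol]] %||%
                   NA_character_)))
    .writeCsvStable(betaTab, file.path(outdir, "pressure_beta.csv"))
    metrics[["beta"]] <- data.frame(id = betaTab$animal_id,
                                    group = betaTab$group,
                                    value = betaTab$beta)
  }

  ## ---- MRI ----
  if (!is.null(cfg$inputs$mri)) {
    curves <- readAreaCSV(cfg$inputs$mri)
    mriTab <- do.call(rbind, lapply(names(curves), function(an) {
      sl <- curves[[an]]
      primary <- sl[["upper"]] %||% sl[[1]]
      secondary <- sl[["lower"]]
      rc <- resampleAreaCurve(primary, fillFrom = secondary)
      k <- strainMetrics(rc)
      data.frame(animal_id = an, asc_slope_mm2_ms = k@ascSlope,
                 total_strain_ms = k@totalStrain)
    }))
    mriMeta <- utils::read.csv(cfg$inputs$mri, stringsAsFactors = FALSE)
    gmap <- mriMeta[!duplicated(mriMeta$animal_id),
                    c("animal_id", groupCol)]
    mriTab <- merge(mriTab, gmap, by = "animal_id", sort = TRUE)
    .writeCsvStable(mriTab, file.path(outdir, "mri_kinetics.csv"))
    metrics[["asc_slope"]] <- data.frame(id = mriTab$animal_id,
                                         group = mriTab[[groupCol]],
                                         value = mriTab$asc_slope_mm2_ms)
    metrics[["total_strain"]] <- data.frame(
      id = mriTab$animal_id, group = mriTab[[groupCol]],
      value = mriTab$total_strain_ms)
  }

  ## ---- PWV ----
  if (!is.null(cfg$inputs$pwv)) {
    pw <- readPWVCSV(cfg$inputs$pwv)
    pw$pwv_m_s <- computePWV(pw$distance_mm, pw$t_aorta_ms,
                             pw$t_femoral_ms)
    .writeCsvStable(pw[order(pw$animal_id), ],
                    file.path(outdir, "pwv.csv"))
    metrics[["pwv"]] <- data.frame(id = pw$animal_id,
                                   group = pw[[groupCol]],
                                   value = pw$pwv_m_s)
  }

  ## ---- elastin ----
  if (!is.null(cfg$inputs$elastin)) {
    el <- utils::read.csv(cfg$inputs$elastin, stringsAsFactors = FALSE)
    elTab <- do.call(rbind, lapply(seq_len(nrow(el)), function(i) {
      img <- readGrayImage(el$path[i])
      res <- tryCatch(
        analyzeRectilinearity(img, pixelSize = el$pixel_size_um[i],
                              medianRadiusPx = pars$median_radius_px %||% 2,
                              ballRadiusPx = pars$ball_radius_px %||% 25,
                              minComponentPx = pars$min_component_px %||% 64),
        error = function(e)
          stop("elastin stage failed on '", el$path[i], "': ",
               conditionMessage(e)))
      data.frame(animal_id = el$animal_id[i],
                 rectilinearity = rectilinearity(res),
                 n_branches = nrow(branches(res)),
                 group = el[[groupCol]][i])
    }))
    .writeCsvStable(elTab, file.path(outdir, "elastin.csv"))
    metrics[["rectilinearity"]] <- data.frame(id = elTab$animal_id,
                                              group = elTab$group,
                                              value = elTab$rectilinearity)
  }

  ## ---- Grubbs exclusion + group comparisons ----
  comparisons <- lapply(names(metrics), function(mn) {
    tab <- metrics[[mn]]
    tab <- tab[is.finite(tab$value), ]
    keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$group),
                          function(ix) {
      if (length(ix) < 3L) return(ix)
      g <- grubbsExclude(tab$value[ix], alpha)
      for (j in g$excluded)
        noteExcl(mn, tab$id[ix[j]],
                 sprintf("Grubbs outlier (G = %.3f, alpha = %g)",
                         g$G[match(j, g$excluded)], alpha))
      ix[setdiff(seq_along(ix), g$excluded)]
    }))
    tab <- tab[sort(keep), ]
    res <- tryCatch(compareGroups(tab, design = "t", alpha = alpha),
                    error = function(e) list(p = NA_real_))
    data.frame(metric = mn, n = nrow(tab), p = res$p,
               significant = isTRUE(res$significant))
  })
  compTab <- do.call(rbind, comparisons)
  .writeCsvStable(compTab, file.path(outdir, "group_comparisons.csv"))

  manifest <- list(
    package = "vasomech",
    version = as.character(utils::packageVersion("vasomech")),
    seed = cfg$seed,
    parameters = pars,
    inputs = cfg$inputs,
    n_exclusions = length(exclusions),
    exclusions = exclusions)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metrics = metrics, comparisons = compTab,
                 manifest = manifest, outputDir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
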