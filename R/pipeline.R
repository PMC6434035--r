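#' Run the breath-hold CVR pipeline on one session
#'
#' Sequences the stages for a single acquisition: spatial smoothing, T2*
#' fit and T2*-weighted echo combination, PW extraction from echo 1,
#' lag-swept breath-hold GLMs for the three dataset variants -- E2
#' (second echo alone), MEC (multi-echo combined) and PW -- and CVR /
#' CBF-ratio / Davis-M maps. The label/control alternation is handled as
#' a design column in the BOLD GLMs; trends are design columns as well,
#' so no destructive preprocessing is applied to the data before fitting.
#'
#' @param series a [MultiEchoSeries-class]
#' @param gmMask,wmMask logical tissue masks
#' @param paradigm the [Paradigm-class] of the acquisition
#' @param cfg configuration list from [fillRunConfig()]
#' @return list with elements `t2s`, `weights`, `tsnr` (per variant),
#'   `activation` (per variant), `maps` (a [CvrMMaps-class] per BOLD
#'   variant), `cvrPw`, `fractionActive`, `contrast`
#' @export
runSession <- function(series, gmMask, wmMask, paradigm = buildParadigm(),
                       cfg = fillRunConfig()) {
  stopifnot(is(series, "MultiEchoSeries"))
  if (nFrames(series) != nFrames(paradigm))
    .stopf("series has %d frames but the paradigm implies %d",
           nFrames(series), nFrames(paradigm))
  brain <- gmMask | wmMask
  shiftsS <- if (is.null(cfg$shifts_s)) defaultShifts(paradigm@trS) else cfg$shifts_s
  bank <- buildRegressorBank(paradigm, shiftsS = shiftsS)

  # T2* fit and weights on the unsmoothed data (fit first, smooth after)
  t2s <- fitT2Star(series)
  weights <- computeWeights(t2s, series@teMs)
  mec <- combineEchoes(series, weights)
  e2 <- new("VoxelSeries",
            data = .echo_array(series, cfg$bold_echo),
            trS = series@trS, labelParity = series@labelParity,
            voxelSizeMm = series@voxelSizeMm)
  pw <- pwFromEcho1(series, cutoffHz = cfg$cutoff_hz,
                    filterOrder = cfg$filter_order)

  if (cfg$fwhm_mm > 0) {
    e2 <- smoothSeries(e2, cfg$fwhm_mm, mask = brain)
    mec <- smoothSeries(mec, cfg$fwhm_mm, mask = brain)
    pw <- smoothSeries(pw, cfg$fwhm_mm, mask = brain)
  }

  pwBank <- pwRegressorBank(bank, cutoffHz = cfg$cutoff_hz,
                            filterOrder = cfg$filter_order,
                            labelParity = series@labelParity)

  actE2 <- lagSweep(e2, bank, mask = brain, trendOrder = cfg$trend_order,
                    alternation = TRUE, prewhiten = cfg$prewhiten,
                    pThreshold = cfg$p_threshold)
  actMec <- lagSweep(mec, bank, mask = brain, trendOrder = cfg$trend_order,
                     alternation = TRUE, prewhiten = cfg$prewhiten,
                     pThreshold = cfg$p_threshold)
  actPw <- lagSweep(pw, pwBank, mask = brain, trendOrder = 0L,
                    alternation = FALSE, prewhiten = FALSE,
                    pThreshold = cfg$p_threshold, shiftsS = bank@shiftsS)

  baseE2 <- baselineMap(e2, actE2, cfg$baseline_mode_bold)
  baseMec <- baselineMap(mec, actMec, cfg$baseline_mode_bold)
  basePw <- baselineMap(pw, actPw, cfg$baseline_mode_pw)

  cvrE2 <- cvrMap(actE2, baseE2)
  cvrMec <- cvrMap(actMec, baseMec)
  cvrPw <- cvrMap(actPw, basePw)
  cbf <- cbfRatioMap(actPw, basePw)
  mapsE2 <- cvrMMaps(cvrE2, cbf, alpha = cfg$alpha, beta = cfg$beta)
  mapsMec <- cvrMMaps(cvrMec, cbf, alpha = cfg$alpha, beta = cfg$beta)

  tsnr <- list(E2 = tsnrMap(e2, actE2), MEC = tsnrMap(mec, actMec),
               PW = tsnrMap(pw, actPw))
  act <- list(E2 = actE2, MEC = actMec, PW = actPw)
  frac <- vapply(act, function(a) fractionActive(a@activeMask, gmMask),
                 numeric(1))
  tryContrast <- function(map) {
    tryCatch(gmWmContrast(map, gmMask, wmMask), error = function(e) NA_real_)
  }
  contrast <- c(cvrE2 = tryContrast(cvrE2), cvrMec = tryContrast(cvrMec),
                mE2 = tryContrast(mapsE2@mPct), mMec = tryContrast(mapsMec@mPct))

  list(t2s = t2s, weights = weights, bank = bank, series = list(E2 = e2, MEC = mec, PW = pw),
       activation = act, tsnr = tsnr, maps = list(E2 = mapsE2, MEC = mapsMec),
       cvrPw = cvrPw, cbfRatio = cbf, fractionActive = frac,
       contrast = contrast, gmMask = gmMask, wmMask = wmMask)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates the end-to-end analysis described by a [readRunConfig()]
#' configuration: load (or simulate) the per-echo data and masks, run
#' [runSession()] per session, and -- when two sessions are present --
#' compute paired retest reports (Dice, repeatability, spatial
#' correlation) for the CVR and M maps of each BOLD variant and the PW
#' CVR map. When `out_dir` is set, maps are written as NIfTI, tables as
#' tab-delimited text, and a stage log with parameters to
#' `pipeline_log.txt`.
#'
#' @param cfg configuration list or path to a YAML file
#' @return list with `sessions` (per-session results), `retest` (named
#'   [RetestReport-class] objects or NULL), `truth` (phantom truth when
#'   simulated), `config`
#' @export
runPipeline <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  cfg <- fillRunConfig(cfg)
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    logLines <<- c(logLines, line)
  }

  paradigm <- do.call(buildParadigm, cfg$paradigm)
  note("paradigm: total %g s, %d functional frames, TR %g s",
       totalDuration(paradigm), nFrames(paradigm), paradigm@trS)

  truth <- NULL
  sessionsIn <- list()
  if (length(cfg$echo_paths)) {
    note("reading %d echoes from NIfTI", length(cfg$echo_paths))
    series <- readMultiEcho(cfg$echo_paths, cfg$te_ms, paradigm@trS,
                            cfg$label_parity)
    gm <- readMask(cfg$gm_mask, dim(series@data)[1:3])
    wm <- readMask(cfg$wm_mask, dim(series@data)[1:3])
    sessionsIn[[1L]] <- list(series = series, gm = gm, wm = wm)
  } else {
    phantomArgs <- cfg$phantom
    phantomArgs$seed <- if (is.null(phantomArgs$seed)) cfg$seed else phantomArgs$seed
    truth <- do.call(phantomTruth, phantomArgs)
    note("simulating phantom: %s grid, noise sd %g, seed %d",
         paste(dim(truth@gmMask), collapse = "x"), truth@noiseSd, truth@seed)
    series <- generatePhantom(truth, paradigm, teMs = cfg$te_ms)
    sessionsIn[[1L]] <- list(series = series, gm = truth@gmMask,
                             wm = truth@wmMask, truth = truth)
    if (cfg$sessions >= 2L) {
      truth2 <- secondSession(truth, cvrJitter = cfg$cvr_jitter,
                              cbfJitter = cfg$cbf_jitter)
      note("simulating second session: cvr jitter %g, cbf jitter %g, seed %d",
           cfg$cvr_jitter, cfg$cbf_jitter, truth2@seed)
      sessionsIn[[2L]] <- list(series = generatePhantom(truth2, paradigm,
                                                        teMs = cfg$te_ms),
                               gm = truth2@gmMask, wm = truth2@wmMask,
                               truth = truth2)
    }
  }

  results <- lapply(seq_along(sessionsIn), function(i) {
    s <- sessionsIn[[i]]
    note("session %d: smoothing %g mm, prewhiten %s, p < %g", i,
         cfg$fwhm_mm, cfg$prewhiten, cfg$p_threshold)
    runSession(s$series, s$gm, s$wm, paradigm, cfg)
  })

  retest <- NULL
  if (length(results) >= 2L) {
    gm <- sessionsIn[[1L]]$gm
    r1 <- results[[1L]]
    r2 <- results[[2L]]
    retest <- list(
      cvrE2 = retestReport(r1$activation$E2@activeMask,
                           r2$activation$E2@activeMask,
                           r1$maps$E2@cvrPct, r2$maps$E2@cvrPct, gm),
      cvrMec = retestReport(r1$activation$MEC@activeMask,
                            r2$activation$MEC@activeMask,
                            r1$maps$MEC@cvrPct, r2$maps$MEC@cvrPct, gm),
      cvrPw = retestReport(r1$activation$PW@activeMask,
                           r2$activation$PW@activeMask,
                           r1$cvrPw, r2$cvrPw, gm),
      mE2 = retestReport(r1$activation$E2@activeMask,
                         r2$activation$E2@activeMask,
                         r1$maps$E2@mPct, r2$maps$E2@mPct, gm),
      mMec = retestReport(r1$activation$MEC@activeMask,
                          r2$activation$MEC@activeMask,
                          r1$maps$MEC@mPct, r2$maps$MEC@mPct, gm))
    note("retest: Dice CVR E2 %.3f, MEC %.3f, PW %.3f",
         retest$cvrE2@dice, retest$cvrMec@dice, retest$cvrPw@dice)
  } else {
    note("single session: retest stage skipped")
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(truth)) writePhantom(truth, sessionsIn[[1L]]$series,
                                      file.path(cfg$out_dir, "phantom"))
    for (i in seq_along(results)) {
      sd <- file.path(cfg$out_dir, sprintf("session%d", i))
      dir.create(sd, showWarnings = FALSE, recursive = TRUE)
      r <- results[[i]]
      vs <- sessionsIn[[i]]$series@voxelSizeMm
      writeVolume(r$t2s@t2starMs, file.path(sd, "t2star_ms.nii.gz"), vs)
      writeVolume(r$t2s@s0, file.path(sd, "s0.nii.gz"), vs)
      for (v in names(r$activation)) {
        a <- r$activation[[v]]
        writeVolume(a@beta, file.path(sd, sprintf("beta_%s.nii.gz", v)), vs)
        writeVolume(a@tstat, file.path(sd, sprintf("tstat_%s.nii.gz", v)), vs)
        writeVolume(a@lagS, file.path(sd, sprintf("lag_s_%s.nii.gz", v)), vs)
        writeVolume(a@r2, file.path(sd, sprintf("r2_%s.nii.gz", v)), vs)
        writeVolume(a@activeMask, file.path(sd, sprintf("active_%s.nii.gz", v)), vs)
      }
      writeVolume(r$maps$E2@cvrPct, file.path(sd, "cvr_e2_pct.nii.gz"), vs)
      writeVolume(r$maps$MEC@cvrPct, file.path(sd, "cvr_mec_pct.nii.gz"), vs)
      writeVolume(r$cvrPw, file.path(sd, "cvr_pw_pct.nii.gz"), vs)
      writeVolume(r$cbfRatio, file.path(sd, "cbf_ratio.nii.gz"), vs)
      writeVolume(r$maps$E2@mPct, file.path(sd, "m_e2_pct.nii.gz"), vs)
      writeVolume(r$maps$MEC@mPct, file.path(sd, "m_mec_pct.nii.gz"), vs)
      tab <- data.frame(variant = names(r$fractionActive),
                        fraction_active_gm = as.numeric(r$fractionActive),
                        tsnr_gm = vapply(r$tsnr, function(m)
                          mean(m[r$gmMask][is.finite(m[r$gmMask])]), numeric(1)))
      utils::write.table(tab, file.path(sd, "summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(retest)) {
      rt <- data.frame(
        map = names(retest),
        dice = vapply(retest, slot, numeric(1), "dice"),
        repeatability = vapply(retest, slot, numeric(1), "repeatability"),
        pearson_r = vapply(retest, slot, numeric(1), "pearsonR"),
        fisher_z = vapply(retest, slot, numeric(1), "fisherZ"))
      utils::write.table(rt, file.path(cfg$out_dir, "retest.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    writeLines(logLines, file.path(cfg$out_dir, "pipeline_log.txt"))
    note("artifacts written to %s", cfg$out_dir)
  }

  list(sessions = results, retest = retest, truth = truth, config = cfg)
}
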