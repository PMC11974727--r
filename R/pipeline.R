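# Orchestration: a config-driven runner tying the modules into the five
# analyses (cortical migration, vertex angles, daughter size, texture,
# ablation mechanics), plus the phenotype-tally arithmetic and a small
# command-line front end. Every run serialises its config into the output
# directory so results are reproducible from the embedded config alone.

#' Tally phenotype proportions
#'
#' Converts a category x condition table of non-negative integer counts
#' into per-condition percentages. The report rounds to the nearest
#' integer percent (so 14 completions out of 206 reads as 7%); exact
#' percentages are retained alongside.
#'
#' @param counts matrix or data.frame of non-negative integer counts with
#'   categories as rows and conditions as columns.
#' @return list with `percent` (rounded), `exact`, `totals`, `counts`.
#' @export
tally_phenotypes <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero total in condition(s): ",
                          paste(colnames(m)[tot == 0], collapse = ", "))
  exact <- sweep(m, 2L, tot, "/") * 100
  list(percent = round(exact), exact = exact, totals = tot, counts = m)
}

#' Run one named analysis stage
#'
#' Executes the stage named in `config$task` with the parameters in the
#' rest of the list, writing result tables (CSV), images (TIFF) and a
#' structured `log.txt` plus the serialised `config.json` into
#' `config$out_dir`. Identical configs produce byte-identical outputs.
#'
#' Tasks: `simulate`, `cortical_ratio`, `angles`, `unwrap`,
#' `daughter_size`, `texture`, `piv`, `kymo`, `tips`, `permtest`,
#' `tally`.
#'
#' @param config named list; see the task implementations for fields.
#' @return list of result objects, invisibly; files under
#'   `config$out_dir`.
#' @export
run_analysis <- function(config) {
  if (is.null(config$task)) stop("config$task is required")
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    cat(paste0(paste(..., sep = " "), "\n"), file = log_path, append = TRUE)
  }
  cat(sprintf("stage=start task=%s version=%s\n", config$task,
              as.character(utils::packageVersion("foamquant"))),
      file = log_path)
  fn <- switch(config$task,
    simulate = task_simulate, cortical_ratio = task_cortical_ratio,
    angles = task_angles, unwrap = task_unwrap,
    daughter_size = task_daughter_size, texture = task_texture,
    piv = task_piv, kymo = task_kymo, tips = task_tips,
    permtest = task_permtest, tally = task_tally,
    stop("unknown task: ", config$task))
  res <- fn(config, out_dir, logf)
  logf("stage=done task=" , config$task)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_stack <- function(config) {
  if (is.null(config$stack)) stop("config$stack (TIFF path) is required")
  if (!file.exists(config$stack)) {
    stop("cannot read stack: ", config$stack, " (file not found)")
  }
  st <- read_tiff(config$stack, pixel_size = config$pixel_size,
                  interval_s = config$interval_s %||% 1)
  if (all(vapply(st$frames, function(f) all(f == 0), logical(1)))) {
    stop("empty stack (all-zero frames): ", config$stack)
  }
  st
}

# fit the sporangium perimeter ellipse from a mask TIFF or, failing that,
# from a 2-class Otsu threshold of the summed stack
stack_ellipse <- function(stack, config) {
  if (!is.null(config$mask)) {
    mk <- read_tiff(config$mask, pixel_size = stack$pixel_size)
    m <- mk$frames[[1L]] > 0.5
  } else {
    s <- Reduce(`+`, stack$frames)
    m <- s > otsu_thresholds(s, n_classes = 2L)
  }
  border <- m & !shift_all_inside(m)
  pts <- which(border, arr.ind = TRUE)
  fit_ellipse(cbind(x = pts[, 2L] - 1, y = pts[, 1L] - 1))
}

task_simulate <- function(config, out_dir, logf) {
  kind <- config$kind %||% stop("simulate needs config$kind")
  args <- config$params %||% list()
  gen <- switch(kind,
    trifurrow = make_trifurrow, foam = make_foam_section,
    migration = make_migration_movie, recoil = make_recoil_movie,
    tips = make_tip_recoil_movie, dissolution = make_dissolution_movie,
    ring = make_ring_layer,
    stop("unknown scene kind: ", kind))
  sc <- do.call(gen, args)
  out_tif <- file.path(out_dir, config[["out"]] %||% "stack.tif")
  if (!is.null(sc$stack)) write_tiff(sc$stack, out_tif)
  else write_tiff(sc$frame, out_tif)
  jsonlite::write_json(sc$truth, file.path(out_dir,
                                           config$truth %||% "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  logf("stage=simulate kind=", kind, "out=", out_tif)
  sc
}

task_cortical_ratio <- function(config, out_dir, logf) {
  st <- load_stack(config)
  E <- stack_ellipse(st, config)
  f <- config$boundary_factor %||% 0.70
  sid <- config$sporangium_id %||% "sp1"
  ser <- stack_cortical_ratio(st, E, f = f, sporangium_id = sid,
                              interval_min = config$interval_min)
  al <- align_to_peak(ser)
  tab <- attr(ser, "counts")
  tab$t_aligned_min <- al$times
  tab <- data.frame(sporangium_id = sid, tab[, c("frame", "t_min")],
                    t_aligned_min = tab$t_aligned_min,
                    tab[, c("n_inner", "n_outer", "ratio")])
  n_undef <- sum(!is.finite(tab$ratio))
  if (n_undef) logf("warning=undefined_ratio frames=", n_undef)
  write_table_csv(tab, file.path(out_dir, config[["out"]] %||% "ratio.csv"))
  list(series = ser, aligned = al, ellipse = E, table = tab)
}

task_angles <- function(config, out_dir, logf) {
  ann <- read_annotations(config$annotations %||%
                            stop("angles needs config$annotations"))
  # labels "<node>:vertex" and "<node>:ray"
  parts <- strsplit(ann$label, ":", fixed = TRUE)
  node <- vapply(parts, `[`, "", 1L)
  role <- vapply(parts, `[`, "", 2L)
  rows <- lapply(unique(node), function(nd) {
    v <- ann[node == nd & role == "vertex", c("x", "y")]
    r <- ann[node == nd & role == "ray", c("x", "y")]
    if (nrow(v) != 1L || nrow(r) != 3L) {
      stop("node ", nd, ": need 1 vertex and 3 ray annotations")
    }
    a <- trifurrow_angles(vertex_annotation(as.numeric(v), as.matrix(r)))
    data.frame(node = nd, angle1_deg = a[1L], angle2_deg = a[2L],
               angle3_deg = a[3L])
  })
  tab <- do.call(rbind, rows)
  write_table_csv(tab, file.path(out_dir, config[["out"]] %||% "angles.csv"))
  tab
}

task_unwrap <- function(config, out_dir, logf) {
  st <- load_stack(config)
  E <- stack_ellipse(st, config)
  mode <- config$mode %||% "log"
  un <- lapply(st$frames, function(f) {
    polar_unwrap(image_frame(f, st$pixel_size), E, mode = mode,
                 n_theta = config$n_theta %||% 360L,
                 n_r = config$n_r %||% 128L)$intensity
  })
  out <- time_lapse(un, st$pixel_size, st$times)
  write_tiff(out, file.path(out_dir, config[["out"]] %||% "unwrapped.tif"))
  out
}

task_daughter_size <- function(config, out_dir, logf) {
  st <- load_stack(config)
  E <- if (!is.null(config$ellipse)) {
    do.call(ellipse_model, config$ellipse)
  } else stack_ellipse(st, config)
  f <- config$factor %||% 0.85
  rows <- lapply(seq_along(st$frames), function(i) {
    prof <- ellipse_band_profile(get_frame(st, i), E, f = f,
                                 band_px = config$band_px %||% 3)
    pk <- detect_peaks(prof,
                       min_prominence_frac = config$min_prominence %||% 0.1,
                       min_distance_um = config$min_distance_um %||% 1)
    if (length(pk$positions) < 2L) {
      logf("warning=too_few_peaks frame=", i)
      return(NULL)
    }
    data.frame(frame = i, diameter_um = daughter_diameters(pk))
  })
  tab <- do.call(rbind, rows)
  write_table_csv(tab, file.path(out_dir, config[["out"]] %||% "sizes.csv"))
  tab
}

task_texture <- function(config, out_dir, logf) {
  st <- load_stack(config)
  ref <- config$ref_frame %||% 1L
  ts <- stack_texture_series(st, reference_index = ref,
                             n_levels = config$n_levels %||% 8L)
  tab <- data.frame(frame = seq_along(ts$asm), t_min = ts$times,
                    asm = ts$asm, relative_homogeneity = ts$relative)
  write_table_csv(tab, file.path(out_dir, config[["out"]] %||% "asm.csv"))
  tab
}

task_piv <- function(config, out_dir, logf) {
  st <- load_stack(config)
  ev <- ablation_event(c(config$ablation_x, config$ablation_y),
                       config$ablation_start, config$ablation_end,
                       config$blank_frames %||% integer(0))
  recs <- piv_recoil_records(
    st, ev, window_px = config$window %||% 32L,
    overlap_px = config$overlap %||% 16L,
    snr_min = config$snr_min %||% 1.3,
    resample_s = config$resample_s,
    dt_mode = config$dt_mode %||% "true",
    mask = if (isTRUE(config$use_mask)) preablation_mask(st, ev))
  write_table_csv(recs, file.path(out_dir, config[["out"]] %||% "radial.csv"))
  summ <- summarize_radial(recs,
                           distance_bins_um = config$distance_bin_um %||% 1,
                           time_bins_s = config$time_bin_s %||%
                             min(diff(st$times)),
                           ci_level = config$ci_level %||% 0.99,
                           n_boot = config$n_boot %||% 2000L,
                           seed = config$seed %||% 1L)
  write_table_csv(summ, file.path(out_dir, "radial_summary.csv"))
  list(records = recs, summary = summ)
}

task_kymo <- function(config, out_dir, logf) {
  st <- load_stack(config)
  ky <- kymograph(st, parse_line(config$line),
                  width_px = config$width %||% 20)
  write_tiff(ky, file.path(out_dir, config[["out"]] %||% "kymo.tif"))
  ky
}

task_tips <- function(config, out_dir, logf) {
  st <- load_stack(config)
  ts <- tip_distance_series(st, parse_line(config$line),
                            width_px = config$width %||% 10)
  write_table_csv(as.data.frame(ts),
                  file.path(out_dir, config[["out"]] %||% "tips.csv"))
  fit <- tryCatch(fit_tip_recoil(ts), error = function(e) {
    logf("warning=tip_fit_failed msg=", conditionMessage(e)); NULL
  })
  if (!is.null(fit)) {
    jsonlite::write_json(fit[c("D0", "A", "tau")],
                         file.path(out_dir, "tip_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(series = ts, fit = fit)
}

task_permtest <- function(config, out_dir, logf) {
  a <- utils::read.csv(config$a)[[1L]]
  b <- utils::read.csv(config$b)[[1L]]
  res <- permutation_test_diff_means(a, b,
                                     alternative = config$alternative %||%
                                       "greater",
                                     n_perm = config$n_perm %||% 9999L,
                                     seed = config$seed %||% 1L)
  jsonlite::write_json(unclass(res), file.path(out_dir, "permtest.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}

task_tally <- function(config, out_dir, logf) {
  tab <- utils::read.csv(config$counts, row.names = 1L, check.names = FALSE)
  res <- tally_phenotypes(tab)
  out <- data.frame(category = rownames(res$percent), res$percent,
                    check.names = FALSE)
  write_table_csv(out, file.path(out_dir, config[["out"]] %||% "tally.csv"))
  res
}

parse_line <- function(line) {
  v <- as.numeric(strsplit(as.character(line), ",")[[1L]])
  if (length(v) != 4L || anyNA(v)) stop("line must be 'x1,y1,x2,y2'")
  list(v[1:2], v[3:4])
}

#' PIV recoil records across a whole ablation stack
#'
#' Runs PIV over consecutive frame pairs (skipping the blank ablation
#' frames), filters vectors by magnitude and SNR, and decomposes them into
#' radial records relative to the ablation site. The pair spanning the
#' ablation gap uses the true timestamp difference by default
#' (`dt_mode = "true"`, ~3 s); `dt_mode = "nominal"` applies the 1-second
#' assumption instead — both published processing variants.
#'
#' @param stack a `time_lapse`.
#' @param event an `ablation_event`.
#' @param window_px,overlap_px PIV window geometry (defaults 32 / 16).
#' @param snr_min SNR filter (default 1.3).
#' @param resample_s optional resampling interval before PIV.
#' @param dt_mode `"true"` or `"nominal"`.
#' @param nominal_dt_s dt used in nominal mode (default 1).
#' @param mask optional logical matrix; window centres outside it are
#'   dropped (the pre-ablation-mask strategy).
#' @return data.frame of radial records (see [radial_velocity()]).
#' @export
piv_recoil_records <- function(stack, event, window_px = 32L,
                               overlap_px = 16L, snr_min = 1.3,
                               resample_s = NULL, dt_mode = c("true",
                                                              "nominal"),
                               nominal_dt_s = 1, mask = NULL) {
  dt_mode <- match.arg(dt_mode)
  stopifnot(inherits(stack, "time_lapse"))
  keep <- setdiff(seq_along(stack$frames), event$blank_frames)
  st <- time_lapse(stack$frames[keep], stack$pixel_size, stack$times[keep])
  if (!is.null(resample_s)) st <- resample_stack(st, resample_s)
  out <- list()
  for (i in seq_len(length(st$frames) - 1L)) {
    dt <- if (dt_mode == "true") st$times[i + 1L] - st$times[i] else
      nominal_dt_s
    fld <- piv_field(st$frames[[i]], st$frames[[i + 1L]],
                     window_px = window_px, overlap_px = overlap_px,
                     dt = dt, pixel_size = st$pixel_size,
                     t_s = st$times[i + 1L])
    if (!is.null(mask)) {
      ctr <- fld$vectors
      ok <- mask[cbind(round(ctr$y_px) + 1L, round(ctr$x_px) + 1L)]
      fld$vectors <- fld$vectors[ok, , drop = FALSE]
    }
    fld <- filter_vectors(fld, snr_min = snr_min)
    if (nrow(fld$vectors)) out[[length(out) + 1L]] <-
        radial_velocity(fld, event)
  }
  if (!length(out)) {
    return(data.frame(t_s = numeric(0), d_um = numeric(0),
                      v_rad_um_s = numeric(0), snr = numeric(0),
                      x_px = numeric(0), y_px = numeric(0)))
  }
  do.call(rbind, out)
}

#' Command-line entry point
#'
#' Parses `subcommand --key value ...` argument lists and dispatches to
#' [run_analysis()]. Installed as the `foamquant` script under
#' `inst/cli/`.
#'
#' @param args character vector (default `commandArgs(TRUE)`).
#' @return the [run_analysis()] result, invisibly.
#' @export
foamquant_cli <- function(args = commandArgs(TRUE)) {
  if (!length(args)) {
    cat("usage: foamquant <task> [--key value ...]\n",
        "tasks: simulate cortical_ratio angles unwrap daughter_size",
        "texture piv kymo tips permtest tally\n")
    return(invisible(NULL))
  }
  task <- gsub("-", "_", args[[1L]])
  rest <- args[-1L]
  config <- list(task = task)
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[[i]]
    if (!startsWith(key, "--")) stop("expected --key, got ", key)
    key <- gsub("-", "_", substring(key, 3L))
    val <- if (i + 1L <= length(rest)) rest[[i + 1L]] else
      stop("missing value for --", key)
    num <- suppressWarnings(as.numeric(val))
    config[[key]] <- if (!is.na(num)) num else val
    i <- i + 2L
  }
  if (!is.null(config$config)) {
    file_cfg <- jsonlite::fromJSON(config$config, simplifyVector = TRUE)
    for (nm in names(file_cfg)) {
      if (is.null(config[[nm]])) config[[nm]] <- file_cfg[[nm]]
    }
  }
  run_analysis(config)
}
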