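#' Configuration for the full analysis pipeline
#'
#' Bundles every stage's parameters. Selections are [atom_selection()]
#' objects; defaults match the synthetic membrane + dimer bundle (membrane
#' phosphorus atoms named `P`, dimer C-alpha atoms on chains A and B,
#' Helix-2 segmentation 92-114 / 114-157, span anchor SER157, displacement
#' centre GLY69).
#'
#' @param input Path of the input trajectory file, or `NULL` when the
#'   trajectory is passed to [run_pipeline()] directly.
#' @param format Trajectory format for [read_trajectory()].
#' @param topology Topology source for `coord_table` input.
#' @param membrane_selection,dimer_selection,donor_selection,lipid_selection
#'   [atom_selection()] objects for the membrane phosphorus atoms, the
#'   dimer atoms, the hydrogen-bond donors and the lipid acceptors.
#' @param region A [fit_region()].
#' @param arm_range,core_range Inclusive residue ranges for segmentation.
#' @param chains Dimer chain ids (length 2).
#' @param span_anchor Span anchor table (see [angle_span_series()]).
#' @param displacement A [displacement_spec()].
#' @param hbond A [hbond_criteria()].
#' @param sasa A [sasa_params()].
#' @param groups List of [residue_group()] for grouped H-bond counts.
#' @param window_fraction Trailing window for curvature statistics.
#' @param pooling Correlation pooling mode.
#' @param sasa_frames Maximum number of evenly spaced frames on which the
#'   chain A / chain B interaction area is computed (0 disables the stage).
#' @param seed Seed recorded for reproducibility of any resampled summary.
#' @param output_dir Directory for CSV/JSON outputs (`NULL` = don't write).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, format = "coord_table", topology = NULL,
                       membrane_selection = atom_selection(name = "P"),
                       dimer_selection = atom_selection(chain = c("A", "B"),
                                                        name = "CA"),
                       donor_selection = atom_selection(
                         chain = c("A", "B"),
                         resname = c("LYS", "ARG", "HIS")),
                       lipid_selection = atom_selection(chain = "M"),
                       region = fit_region(),
                       arm_range = c(114, 157), core_range = c(92, 114),
                       chains = c("A", "B"),
                       span_anchor = data.frame(chain = c("A", "B"),
                                                resno = c(157, 157),
                                                name = c("CA", "CA"),
                                                stringsAsFactors = FALSE),
                       displacement = displacement_spec(),
                       hbond = hbond_criteria(), sasa = sasa_params(),
                       groups = list(), window_fraction = 1 / 3,
                       pooling = "pooled", sasa_frames = 0, seed = 1,
                       output_dir = NULL) {
  structure(list(input = input, format = format, topology = topology,
                 membrane_selection = membrane_selection,
                 dimer_selection = dimer_selection,
                 donor_selection = donor_selection,
                 lipid_selection = lipid_selection, region = region,
                 arm_range = arm_range, core_range = core_range,
                 chains = chains, span_anchor = span_anchor,
                 displacement = displacement, hbond = hbond, sasa = sasa,
                 groups = groups, window_fraction = window_fraction,
                 pooling = pooling, sasa_frames = sasa_frames,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Validate a run configuration against a trajectory
#'
#' Checks every selection and residue reference and returns the aggregated
#' list of problems (it does not stop at the first).
#'
#' @param config A [run_config()].
#' @param traj The [trajectory()] the pipeline will analyse.
#' @return Character vector of error messages; empty when valid.
#' @export
validate_config <- function(config, traj) {
  errs <- character(0)
  a <- traj$atoms
  if (length(select_atoms(traj, config$membrane_selection)) == 0) {
    errs <- c(errs, "membrane selection resolves to no atoms")
  }
  if (length(select_atoms(traj, config$dimer_selection)) == 0) {
    errs <- c(errs, "dimer selection resolves to no atoms")
  }
  for (ch in config$chains) {
    for (rr in list(c("arm", config$arm_range), c("core", config$core_range))) {
      range_i <- as.integer(rr[2:3])
      have <- a$resno[a$chain == ch & a$name == "CA"]
      missing <- setdiff(seq(range_i[1], range_i[2]), have)
      if (length(missing) > 0) {
        errs <- c(errs, paste0(rr[1], " range chain ", ch,
                               ": missing residue(s) ",
                               paste(utils::head(missing, 5), collapse = ", ")))
      }
    }
  }
  for (k in seq_len(nrow(config$span_anchor))) {
    r <- config$span_anchor[k, ]
    if (!any(a$chain == r$chain & a$resno == r$resno & a$name == r$name)) {
      errs <- c(errs, paste0("span anchor not found: chain ", r$chain,
                             " residue ", r$resno, " atom ", r$name))
    }
  }
  for (k in seq_len(nrow(config$displacement$center_residues))) {
    r <- config$displacement$center_residues[k, ]
    if (!any(a$chain == r$chain & a$resno == r$resno & a$name == r$name)) {
      errs <- c(errs, paste0("displacement centre not found: chain ",
                             r$chain, " residue ", r$resno, " atom ", r$name))
    }
  }
  for (g in config$groups) {
    msg <- tryCatch({ check_group(traj, g); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(msg)) errs <- c(errs, msg)
  }
  errs
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

run_stage <- function(report, stage, fun) {
  res <- tryCatch(list(ok = TRUE, value = fun(), error = NULL),
                  error = function(e) list(ok = FALSE, value = NULL,
                                           error = conditionMessage(e)))
  if (res$ok) {
    stage_log(stage, "completed")
  } else {
    stage_log(stage, paste("FAILED:", res$error))
  }
  report$stages[[stage]] <- list(ok = res$ok, error = res$error)
  report$values[[stage]] <- res$value
  report
}

write_stage_csv <- function(df, output_dir, name) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(output_dir, name)
  df2 <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.10g", col) else col
  }), stringsAsFactors = FALSE)
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, each isolated so a failure does not stop independent stages:
#' `align` (membrane plane to z, dimer axis to x), `curvature` (per-frame
#' circle fits + trailing-window statistics), `geometry` (angle/span series
#' and Pearson correlations), `hbonds` (grouped counts; skipped silently
#' when the donor selection is empty), `displacement` (horizontal lipid
#' distances), `interaction_area` (chain A vs chain B on a frame
#' subsample, when `sasa_frames > 0`). Per-frame CSVs and a JSON report
#' are written when `output_dir` is set. Progress goes to `message()`
#' (stderr); results never do.
#'
#' @param config A [run_config()].
#' @param traj Optional pre-loaded [trajectory()] (otherwise read from
#'   `config$input`).
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config, traj = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(traj)) {
    if (is.null(config$input)) stop("no input path and no trajectory given")
    traj <- read_trajectory(config$input, config$format,
                            topology = config$topology)
  }
  errs <- validate_config(config, traj)

  report <- list(config = config, n_frames = n_frames(traj),
                 n_atoms = n_atoms(traj), validation = errs,
                 stages = list(), values = list())
  class(report) <- "run_report"

  mem <- select_atoms(traj, config$membrane_selection)
  dim_sel <- select_atoms(traj, config$dimer_selection)

  aligned <- traj
  report <- run_stage(report, "align", function() {
    aligned <<- align_frames(traj, mem, dim_sel)
    list(n_frames = n_frames(aligned))
  })

  report <- run_stage(report, "curvature", function() {
    cs <- curvature_series(aligned, mem, config$region, dim_sel,
                           config$window_fraction)
    write_stage_csv(cs, config$output_dir, "curvature.csv")
    list(window_mean_kappa_nm = attr(cs, "window_mean"),
         window_sd_kappa_nm = attr(cs, "window_sd"),
         n_excluded = attr(cs, "n_excluded"), series = cs)
  })

  report <- run_stage(report, "geometry", function() {
    segs <- default_segments(config$arm_range, config$core_range,
                             config$chains)
    as <- angle_span_series(aligned, segs, config$span_anchor)
    write_stage_csv(as, config$output_dir, "geometry.csv")
    ct <- correlation_summary(as, pooling = config$pooling)
    write_stage_csv(ct, config$output_dir, "correlations.csv")
    list(correlations = ct, n_excluded = attr(as, "n_excluded"),
         series = as)
  })

  donors <- select_atoms(traj, config$donor_selection)
  lipids <- select_atoms(traj, config$lipid_selection)
  if (length(donors) > 0 && length(lipids) > 0) {
    report <- run_stage(report, "hbonds", function() {
      hs <- grouped_hbond_series(aligned, config$groups, donors, lipids,
                                 config$hbond)
      write_stage_csv(hs$counts, config$output_dir, "hbonds.csv")
      gmeans <- colMeans(hs$counts[, setdiff(names(hs$counts),
                                             c("frame", "time_ps")),
                                   drop = FALSE])
      list(mean_counts = as.list(gmeans), mode = hs$mode, series = hs)
    })
  }

  report <- run_stage(report, "displacement", function() {
    ds <- horizontal_displacement_series(aligned, config$displacement)
    write_stage_csv(ds, config$output_dir, "displacement.csv")
    slope <- if (nrow(ds) >= 3) {
      stats::coef(stats::lm(mean_distance_A ~ time_ps, data = ds))[[2]]
    } else NA_real_
    list(trend_slope_A_per_ps = slope,
         start_A = ds$mean_distance_A[1],
         end_A = ds$mean_distance_A[nrow(ds)], series = ds)
  })

  if (config$sasa_frames > 0) {
    report <- run_stage(report, "interaction_area", function() {
      ia_frames <- unique(round(seq(1, n_frames(traj),
                                    length.out = min(config$sasa_frames,
                                                     n_frames(traj)))))
      bA <- select_atoms(traj, chain = config$chains[1])
      bB <- select_atoms(traj, chain = config$chains[2])
      vals <- vapply(ia_frames, function(f) {
        interaction_area(aligned, bA, bB, config$sasa, frame = f)$area
      }, numeric(1))
      df <- data.frame(frame = ia_frames, area_A2 = vals)
      write_stage_csv(df, config$output_dir, "interaction_area.csv")
      list(mean_area_A2 = mean(vals), frames = ia_frames, series = df)
    })
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_summary(report),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# machine-readable stage summaries (no bulky per-frame series)
report_summary <- function(report) {
  vals <- lapply(report$values, function(v) {
    if (is.null(v)) return(NULL)
    v$series <- NULL
    v
  })
  cfg <- report$config
  list(package_version = as.character(utils::packageVersion("bartraj")),
       n_frames = report$n_frames, n_atoms = report$n_atoms,
       validation_errors = report$validation,
       config = list(format = cfg$format,
                     region = unclass(cfg$region),
                     arm_range = cfg$arm_range, core_range = cfg$core_range,
                     window_fraction = cfg$window_fraction,
                     pooling = cfg$pooling,
                     hbond = unclass(cfg$hbond),
                     sasa = list(probe_radius = cfg$sasa$probe_radius,
                                 n_sphere_points = cfg$sasa$n_sphere_points),
                     seed = cfg$seed),
       stages = report$stages, results = vals)
}

#' Render a run report as markdown text
#'
#' One section per executed stage, in pipeline order; numbers match the
#' JSON report to printed precision. Failed stages appear with their error.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
report_render <- function(report) {
  stopifnot(inherits(report, "run_report"))
  lines <- c("# Trajectory analysis report", "",
             sprintf("- frames: %d, atoms: %d", report$n_frames,
                     report$n_atoms))
  if (length(report$validation) > 0) {
    lines <- c(lines, "- validation errors:",
               paste0("  - ", report$validation))
  }
  order_stages <- c("align", "curvature", "geometry", "hbonds",
                    "displacement", "interaction_area")
  for (st in intersect(order_stages, names(report$stages))) {
    s <- report$stages[[st]]
    lines <- c(lines, "", paste0("## ", st), "")
    if (!s$ok) {
      lines <- c(lines, paste0("FAILED: ", s$error))
      next
    }
    v <- report$values[[st]]
    lines <- c(lines, switch(
      st,
      align = sprintf("aligned %d frames", v$n_frames),
      curvature = sprintf(
        "window mean kappa = %.4f nm^-1 (sd %.4f, %d frames excluded)",
        v$window_mean_kappa_nm, v$window_sd_kappa_nm, v$n_excluded),
      geometry = c(sprintf("excluded frames: %d", v$n_excluded),
                   sprintf("Pearson r(%s, %s) = %.3f", v$correlations$x,
                           v$correlations$y, v$correlations$r)),
      hbonds = sprintf("mean counts: %s",
                       paste(names(v$mean_counts),
                             sprintf("%.2f", unlist(v$mean_counts)),
                             sep = " = ", collapse = ", ")),
      displacement = sprintf(
        "mean horizontal distance %.2f -> %.2f A (slope %.3g A/ps)",
        v$start_A, v$end_A, v$trend_slope_A_per_ps),
      interaction_area = sprintf("mean interaction area = %.2f A^2",
                                 v$mean_area_A2)))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(report_render(x), sep = "\n")
  invisible(x)
}
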