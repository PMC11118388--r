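#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. Residue spans and
#' the kink pivot come from the receptor preset (inferred from the
#' topology when not given) and can be overridden individually.
#'
#' @param trajectory an \code{md_trajectory}, or a trajectory file path.
#' @param topology a \code{bead_topology} or structure file path
#'   (required when \code{trajectory} is a path).
#' @param receptor optional "IR"/"IGF1R" preset override.
#' @param out_dir output directory.
#' @param cutoff dimerization cutoff, nm.
#' @param probe SASA probe radius, nm.
#' @param n_points SASA quadrature points per bead.
#' @param bsa_stride evaluate BSA every this-many frames (default chosen
#'   so at most ~50 frames are evaluated).
#' @param cluster_cutoff Daura RMSD cutoff, nm.
#' @param cluster_stride stride over dimerized frames for clustering.
#' @param bin_width PMF bin width, degrees.
#' @param temperature K.
#' @param seed RNG seed stamped into outputs.
#' @param thresholds packing-mode thresholds.
#' @return a \code{run_config} list.
#' @export
run_config <- function(trajectory, topology = NULL, receptor = NULL,
                       out_dir = "tmdimer_out", cutoff = 1.3, probe = 0.185,
                       n_points = 960, bsa_stride = NULL,
                       cluster_cutoff = 0.9, cluster_stride = 1,
                       bin_width = 2.5, temperature = 300, seed = 1,
                       thresholds = packing_thresholds()) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full dimerization analysis pipeline
#'
#' One pass over the trajectory producing, in \code{out_dir}: the
#' per-frame geometry table, the state table (dimerized flag + packing
#' mode), tilt and crossing-angle free-energy profiles, per-chain RMSF,
#' Daura clustering of dimerized frames with GRO representatives, the
#' residue contact map, a (strided) BSA series and a \code{summary.json}
#' holding the headline numbers, the effective configuration and its
#' hash. On a single-chain (monomeric) system only the tilt and RMSF
#' stages run and pair stages are skipped with a notice. If a stage
#' fails, completed outputs are kept with a \code{.partial} suffix and
#' the error names the stage.
#'
#' @param config a \code{run_config}.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  out <- function(name) file.path(cfg$out_dir, name)
  note <- function(...) message("[tmdimer] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (f in written) if (file.exists(f))
        file.rename(f, paste0(f, ".partial"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(cfg$seed)
  traj <- stage("input", {
    if (inherits(cfg$trajectory, "md_trajectory")) cfg$trajectory
    else {
      top <- if (inherits(cfg$topology, "bead_topology")) cfg$topology
      else read_structure(cfg$topology)$topology
      read_trajectory(cfg$trajectory, top)
    }
  })
  top <- traj$topology
  preset <- if (!is.null(cfg$receptor)) tmd_preset(cfg$receptor)
  else tryCatch(infer_preset(top), error = function(e) NULL)
  chains <- unique(top$chain_id)
  monomer <- length(chains) < 2
  summary_list <- list(n_frames = n_frames(traj), seed = cfg$seed,
                       monomer = monomer)

  if (monomer) {
    note("single chain detected: running tilt/RMSF stages only, %s",
         "skipping pair stages")
    span <- if (!is.null(preset)) as_span(preset$tilt_span)
    else range(top$residue_number)
    th <- stage("tilt", vapply(seq_len(n_frames(traj)), function(i)
      tilt_angle(fit_axis(get_frame(traj, i), top, chains[1], span)),
      numeric(1)))
    pmf <- stage("pmf", pmf_with_replicates(list(th), "theta",
                                            cfg$bin_width,
                                            temperature = cfg$temperature))
    write_metrics_table(as.data.frame(pmf), out("pmf_theta.tsv"),
                        units = c(bin_center = "deg",
                                  free_energy = "kcal/mol"))
    written <- c(written, out("pmf_theta.tsv"))
    rp <- stage("rmsf", rmsf(traj, chains[1],
                             if (!is.null(preset)) as_span(preset$tilt_span)
                             else NULL))
    write_metrics_table(rp, out("rmsf.tsv"), units = c(rmsf = "nm"))
    written <- c(written, out("rmsf.tsv"))
    summary_list$pmf_theta_minimum <- summary(pmf)$minimum
  } else {
    geom <- stage("geometry", pair_geometry(traj, preset = preset))
    write_metrics_table(geom, out("geometry.tsv"),
                        units = c(time = "ps", dhh = "nm", theta1 = "deg",
                                  theta2 = "deg", omega = "deg",
                                  kink1 = "deg", kink2 = "deg",
                                  min_approach = "nm"))
    written <- c(written, out("geometry.tsv"))

    stt <- stage("states", state_table(geom, cutoff = cfg$cutoff,
                                       thresholds = cfg$thresholds))
    write_metrics_table(stt$table, out("states.tsv"),
                        units = c(time = "ps", dhh = "nm"))
    written <- c(written, out("states.tsv"))
    st <- stt$state

    pmf_t <- stage("pmf", pmf_with_replicates(list(c(geom$theta1,
                                                     geom$theta2)),
                                              "theta", cfg$bin_width,
                                              temperature = cfg$temperature))
    write_metrics_table(as.data.frame(pmf_t), out("pmf_theta.tsv"),
                        units = c(bin_center = "deg",
                                  free_energy = "kcal/mol"))
    written <- c(written, out("pmf_theta.tsv"))
    pmf_o <- NULL
    if (any(st$dimerized)) {
      pmf_o <- stage("pmf", pmf_with_replicates(
        list(geom$omega[st$dimerized]), "omega", cfg$bin_width,
        temperature = cfg$temperature))
      write_metrics_table(as.data.frame(pmf_o), out("pmf_omega.tsv"),
                          units = c(bin_center = "deg",
                                    free_energy = "kcal/mol"))
      written <- c(written, out("pmf_omega.tsv"))
    }

    rp <- stage("rmsf", do.call(rbind, lapply(chains, function(ch)
      rmsf(traj, ch, if (!is.null(preset)) as_span(preset$tilt_span)
           else NULL))))
    write_metrics_table(rp, out("rmsf.tsv"), units = c(rmsf = "nm"))
    written <- c(written, out("rmsf.tsv"))

    cl <- NULL
    if (sum(st$dimerized) >= 2) {
      cl <- stage("clustering", cluster_dimer_states(
        traj, st, cutoff = cfg$cluster_cutoff, stride = cfg$cluster_stride,
        geometry = geom, representatives_dir = out("representatives")))
      jsonlite::write_json(list(populations = cl$clusters$populations,
                                centers = cl$summary$center_frame,
                                cutoff = cfg$cluster_cutoff),
                           out("clusters.json"), auto_unbox = TRUE,
                           digits = NA)
      written <- c(written, out("clusters.json"))
      cm <- stage("contacts", contact_map(traj, st))
      utils::write.table(unclass(cm), out("contacts.tsv"), sep = "\t",
                         quote = FALSE)
      written <- c(written, out("contacts.tsv"))
    } else note("fewer than 2 dimerized frames: skipping clustering/contacts")

    bsa_stride <- cfg$bsa_stride
    if (is.null(bsa_stride))
      bsa_stride <- max(1L, ceiling(n_frames(traj) / 50))
    bsa_frames <- seq(1, n_frames(traj), by = bsa_stride)
    ss <- stage("bsa", surface_series(traj, bsa_frames, probe = cfg$probe,
                                      n_points = cfg$n_points))
    write_metrics_table(ss, out("bsa.tsv"),
                        units = c(time = "ps", bsa = "nm2"))
    written <- c(written, out("bsa.tsv"))

    modes <- stt$table$mode[stt$table$dimerized]
    summary_list <- c(summary_list, list(
      first_passage_frame = st$first_passage_frame,
      first_passage_time_ps = if (!is.na(st$first_passage_frame))
        st$times[st$first_passage_frame] else NA,
      dimerized_fraction = mean(st$dimerized),
      dominant_mode = if (length(modes))
        names(sort(table(modes), decreasing = TRUE))[1] else NA,
      pmf_theta_minimum = summary(pmf_t)$minimum,
      pmf_omega_minimum = if (!is.null(pmf_o)) summary(pmf_o)$minimum
      else NA,
      top_clusters = if (!is.null(cl))
        utils::head(cl$clusters$populations, 3) else NULL))
  }

  eff <- cfg
  eff$trajectory <- if (is.character(cfg$trajectory)) cfg$trajectory
  else "<in-memory trajectory>"
  eff$topology <- if (is.character(cfg$topology)) cfg$topology
  else "<in-memory topology>"
  eff$thresholds <- cfg$thresholds
  cfg_json <- jsonlite::toJSON(unclass(eff), auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  summary_list$config <- jsonlite::fromJSON(cfg_json)
  summary_list$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  jsonlite::write_json(summary_list, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(summary_list)
}
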