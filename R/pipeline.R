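#' Default pipeline configuration
#'
#' Nested list mirroring the stage parameters: `genome` (length, gc,
#' circular, name), `sites` (n_sites, strength/satellite parameters,
#' use_motif), `simulate` (a [simulation_config()] parameter block), `call`
#' (alpha, min_height, stagger, jitter, min_support, tolerance,
#' satellite_window), `motif` (halfwidth), `stats` (bin, regions). A global
#' `seed` drives every stage through [derive_seed()].
#'
#' @return A named list of defaults; override entries via a YAML config file
#'   (see [read_pipeline_config()]).
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "toposeq_out",
    genome = list(length = 2e5, gc = 0.5, circular = TRUE,
                  name = "chr_synth", fasta = NULL),
    sites = list(n_sites = 40L, strength_meanlog = log(100),
                 strength_sdlog = 0.5, satellites = 0L, use_motif = TRUE,
                 motif_halfwidth = 8L, motif_prob = 0.8),
    simulate = list(background_fragments = 20000L,
                    fragment_length_min = 200L, fragment_length_max = 800L,
                    capture_efficiency_3p = 0.8, capture_efficiency_5p = 0.5,
                    n_replicates = 3L, stagger = 5L, mock_dilution = 1 / 20),
    call = list(alpha = 1e-5, min_height = 5, jitter = 0L, min_support = 2L,
                tolerance = 0L, satellite_window = 100L, pseudocount = 1),
    motif = list(halfwidth = 13L),
    stats = list(bin = 10000L, regions = NULL, tus = NULL,
                 flank = 1000L, body_bins = 50L, strata = 0.1),
    manifest = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file, merges it over [default_pipeline_config()], and
#' validates it: every referenced file must exist and sample labels in a
#' fragment manifest must be unique. Validation failures abort before any
#' stage runs.
#'
#' @param path YAML config path, or a config list to validate in place.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    merge_config(default_pipeline_config(), yaml::read_yaml(path))
  } else {
    merge_config(default_pipeline_config(), path)
  }
  if (!is.null(cfg$genome$fasta) && !file.exists(cfg$genome$fasta)) {
    abort(sprintf("Config error: genome FASTA '%s' does not exist.",
                  cfg$genome$fasta))
  }
  if (!is.null(cfg$manifest)) {
    labs <- vapply(cfg$manifest, function(m) m$label, character(1))
    if (anyDuplicated(labs)) abort("Config error: duplicate sample labels.")
    for (m in cfg$manifest) {
      if (!file.exists(m$file)) {
        abort(sprintf("Config error: fragment file '%s' does not exist.",
                      m$file))
      }
    }
  }
  if (!is.null(cfg$stats$tus) && is.character(cfg$stats$tus) &&
      !file.exists(cfg$stats$tus)) {
    abort(sprintf("Config error: TU annotation '%s' does not exist.",
                  cfg$stats$tus))
  }
  cfg
}

pipeline_log <- function(con, ...) {
  writeLines(sprintf(...), con)
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Executes simulate -> tracks -> call -> motif -> stats in order, writing
#' every output under `outdir` and recording each file with its MD5 checksum
#' in `manifest.tsv`. The log records package version, seeds and resolved
#' parameters. A stage failure aborts with the failing stage named, leaving
#' partial outputs plus a `FAILED.<stage>` marker file.
#'
#' @param config A config list or YAML path (see [read_pipeline_config()]).
#' @param outdir Output directory (overrides the config entry).
#' @return The manifest tibble (`file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- read_pipeline_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$outdir, "log.txt")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  pipeline_log(con, "toposeqr %s | R %s",
               as.character(utils::packageVersion("toposeqr")),
               paste(R.version$major, R.version$minor, sep = "."))
  pipeline_log(con, "started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  pipeline_log(con, "seed: %d", cfg$seed)
  pipeline_log(con, "resolved config:\n%s", yaml::as.yaml(cfg))

  outputs <- character()
  emit <- function(path) outputs[[length(outputs) + 1L]] <<- path
  stage <- "init"
  run_stage <- function(name, fun) {
    stage <<- name
    pipeline_log(con, "[stage %s] start", name)
    res <- fun()
    pipeline_log(con, "[stage %s] done", name)
    res
  }

  result <- tryCatch({
    # --- simulate ---------------------------------------------------------
    sim <- run_stage("simulate", function() {
      scfg <- simulation_config(
        seed = cfg$seed,
        genome_length = cfg$genome$length,
        n_sites = cfg$sites$n_sites,
        strength_meanlog = cfg$sites$strength_meanlog,
        strength_sdlog = cfg$sites$strength_sdlog,
        fragment_length_min = cfg$simulate$fragment_length_min,
        fragment_length_max = cfg$simulate$fragment_length_max,
        background_fragments = cfg$simulate$background_fragments,
        capture_efficiency_3p = cfg$simulate$capture_efficiency_3p,
        capture_efficiency_5p = cfg$simulate$capture_efficiency_5p,
        n_replicates = cfg$simulate$n_replicates,
        stagger = cfg$simulate$stagger,
        mock_dilution = cfg$simulate$mock_dilution
      )
      genome <- if (!is.null(cfg$genome$fasta)) {
        read_genome_fasta(cfg$genome$fasta, circular = cfg$genome$circular)
      } else {
        generate_genome(cfg$genome$length, gc = cfg$genome$gc,
                        circular = cfg$genome$circular,
                        seed = derive_seed(cfg$seed, "genome"),
                        name = cfg$genome$name)
      }
      motif <- if (isTRUE(cfg$sites$use_motif)) {
        determinant_motif(cfg$sites$motif_halfwidth, cfg$sites$motif_prob)
      }
      planted <- plant_sites(genome, cfg$sites$n_sites,
                             strengths = c(meanlog = cfg$sites$strength_meanlog,
                                           sdlog = cfg$sites$strength_sdlog),
                             motif = motif, stagger = scfg$stagger,
                             satellites = cfg$sites$satellites,
                             seed = derive_seed(cfg$seed, "sites"))
      genome <- planted$genome
      frags <- simulate_experiment(genome, planted$sites, scfg)
      emit(write_genome_fasta(genome, file.path(cfg$outdir, "genome.fasta")))
      paths <- write_truth(planted$sites,
                           file.path(cfg$outdir, "truth.bed"),
                           file.path(cfg$outdir, "truth.tsv"),
                           chrom = genome$name)
      emit(paths[["bed"]]); emit(paths[["tsv"]])
      emit(write_fragments_tsv(frags, file.path(cfg$outdir, "fragments.tsv")))
      list(genome = genome, sites = planted$sites, frags = frags, scfg = scfg)
    })

    # --- tracks -----------------------------------------------------------
    tracks <- run_stage("tracks", function() {
      labs <- unique(sim$frags$sample)
      tr <- lapply(labs, function(lb) {
        compute_tracks(sim$frags, sim$genome$length,
                       circular = sim$genome$circular, sample = lb)
      })
      names(tr) <- labs
      for (lb in grep("\\+Cfx\\+IP", labs, value = TRUE)) {
        safe <- gsub("[^A-Za-z0-9]+", "_", lb)
        emit(write_track_bedgraph(
          tr[[lb]]$n3e_fwd, sim$genome$name,
          file.path(cfg$outdir, paste0("n3e_fwd_", safe, ".bedgraph"))))
        emit(write_track_bedgraph(
          tr[[lb]]$n3e_rev, sim$genome$name,
          file.path(cfg$outdir, paste0("n3e_rev_", safe, ".bedgraph"))))
      }
      tr
    })

    # --- call -------------------------------------------------------------
    tcs <- run_stage("call", function() {
      reps <- seq_len(cfg$simulate$n_replicates)
      sets <- lapply(reps, function(r) {
        call_tcs(tracks[[paste0("+Cfx+IP_R", r)]],
                 tracks[[paste0("-Cfx+IP_R", r)]],
                 alpha = cfg$call$alpha, min_height = cfg$call$min_height,
                 stagger = cfg$simulate$stagger, jitter = cfg$call$jitter,
                 pseudocount = cfg$call$pseudocount)
      })
      rec <- reconcile_replicates(sets, min_support = cfg$call$min_support,
                                  tolerance = cfg$call$tolerance)
      rec <- classify_primary_satellite(rec,
                                        window = cfg$call$satellite_window)
      emit(write_tcs_bed(rec, sim$genome$name,
                         file.path(cfg$outdir, "tcs.bed"),
                         overhang = cfg$simulate$stagger - 1L))
      emit(write_tcs_tsv(rec, file.path(cfg$outdir, "tcs.tsv")))
      orphans <- bind_rows(lapply(sets, function(s) attr(s, "orphans")))
      emit(write_tcs_tsv(orphans, file.path(cfg$outdir, "orphans.tsv")))
      rec
    })

    # --- motif ------------------------------------------------------------
    run_stage("motif", function() {
      if (nrow(tcs) == 0) {
        pipeline_log(con, "[stage motif] no sites called; skipped")
        return(NULL)
      }
      win <- extract_windows(sim$genome, tcs,
                             halfwidth = cfg$motif$halfwidth)
      pfm <- build_pfm(win)
      emit(write_motif_tsv(pfm, file.path(cfg$outdir, "motif.tsv")))
      emit(write_motif_jaspar(pfm, file.path(cfg$outdir, "motif.jaspar")))
      gp <- gc_profile(sim$genome, tcs,
                       halfwidth = min(2000L, sim$genome$length %/% 4L))
      readr::write_tsv(gp, file.path(cfg$outdir, "gc_profile.tsv"))
      emit(file.path(cfg$outdir, "gc_profile.tsv"))
      pfm
    })

    # --- stats ------------------------------------------------------------
    run_stage("stats", function() {
      if (nrow(tcs) == 0) {
        pipeline_log(con, "[stage stats] no sites called; skipped")
        return(NULL)
      }
      bins <- bin_density(tcs, cfg$stats$bin, sim$genome$length)
      readr::write_tsv(bins, file.path(cfg$outdir, "bin_density.tsv"))
      emit(file.path(cfg$outdir, "bin_density.tsv"))
      regions <- cfg$stats$regions
      if (is.null(regions)) {
        regions <- tibble(name = "first_tenth", start = 0L,
                          end = as.integer(sim$genome$length %/% 10L))
      } else if (is.character(regions)) {
        regions <- read_regions_bed(regions)
      } else {
        regions <- as_tibble(do.call(rbind.data.frame, regions))
      }
      enr <- region_enrichment(tcs, regions, sim$genome$length)
      readr::write_tsv(enr, file.path(cfg$outdir, "region_enrichment.tsv"))
      emit(file.path(cfg$outdir, "region_enrichment.tsv"))
      if (!is.null(cfg$stats$tus)) {
        tus <- if (is.character(cfg$stats$tus)) read_tu_tsv(cfg$stats$tus)
          else as_tibble(cfg$stats$tus)
        fe <- normalize_tracks(tracks[["+Cfx+IP_R1"]],
                               tracks[["-Cfx-IP_R1"]], field = "n3e")
        mg <- metagene(fe, tus, flank = cfg$stats$flank,
                       body_bins = cfg$stats$body_bins,
                       strata = cfg$stats$strata)
        readr::write_tsv(mg, file.path(cfg$outdir, "metagene.tsv"))
        emit(file.path(cfg$outdir, "metagene.tsv"))
      }
      enr
    })

    manifest <- tibble(
      file = basename(unlist(outputs)),
      md5 = unname(tools::md5sum(unlist(outputs)))
    ) |> arrange(.data$file)
    readr::write_tsv(manifest, file.path(cfg$outdir, "manifest.tsv"))
    pipeline_log(con, "pipeline complete: %d output files", nrow(manifest))
    manifest
  }, error = function(e) {
    marker <- file.path(cfg$outdir, paste0("FAILED.", stage))
    writeLines(conditionMessage(e), marker)
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
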