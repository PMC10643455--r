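# End-to-end orchestration: plain-text config, validation, stage running,
# combined report. All randomness derives from one root seed.

#' Read a run configuration
#'
#' YAML key-value hierarchy. Top-level keys: `seed` (root seed), `out`
#' (output directory), `log_level`, `stages` (named list; any of
#' `sequences`, `chromatogram`, `spectra`, `geometry`, `em`, each either
#' `simulate: {...}` parameters or explicit input paths). Unknown
#' top-level keys are rejected.
#'
#' @param file YAML path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a config list built in code.
#' @export
as_run_config <- function(config) {
  allowed <- c("seed", "out", "log_level", "stages")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$log_level <- config$log_level %||% "info"
  if (is.null(config$stages) || !length(config$stages)) {
    abort("config must request at least one stage")
  }
  known_stages <- c("sequences", "chromatogram", "spectra", "geometry", "em")
  bad <- setdiff(names(config$stages), known_stages)
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  class(config) <- "run_config"
  config
}

#' Validate pipeline inputs without running anything
#'
#' Checks referenced files exist and are well-formed (readable layouts,
#' monotone grids, required channels). Never modifies data.
#'
#' @param config a `run_config`.
#' @return tibble of failures (`stage`, `problem`); zero rows when valid.
#' @export
validate_inputs <- function(config) {
  fails <- list()
  note <- function(stage, problem) {
    fails[[length(fails) + 1L]] <<- tibble(stage = stage, problem = problem)
  }
  st <- config$stages
  check_file <- function(stage, path) {
    if (!is.null(path) && !file.exists(path)) {
      note(stage, sprintf("missing file: %s", path)); FALSE
    } else !is.null(path)
  }

  if (!is.null(st$chromatogram) && is.null(st$chromatogram$simulate)) {
    for (side in c("pink", "purple")) {
      if (check_file("chromatogram", st$chromatogram[[side]])) {
        tr <- tryCatch(read_chromatogram(st$chromatogram[[side]]),
                       error = function(e) conditionMessage(e))
        if (is.character(tr)) note("chromatogram", tr)
        else {
          if (!"560" %in% names(tr)) note("chromatogram",
                                          sprintf("%s: no 560 nm channel", side))
          if (isTRUE(st$chromatogram$rescue_saturation) &&
              !"280" %in% names(tr)) {
            note("chromatogram",
                 sprintf("%s: saturation rescue requested but no 280 nm channel",
                         side))
          }
        }
      }
    }
  }
  if (!is.null(st$sequences) && is.null(st$sequences$simulate)) {
    if (check_file("sequences", st$sequences$fasta)) {
      tryCatch(read_alpha_fasta(st$sequences$fasta),
               error = function(e) note("sequences", conditionMessage(e)))
    }
  }
  if (!is.null(st$spectra) && is.null(st$spectra$simulate)) {
    if (check_file("spectra", st$spectra$eem)) {
      tryCatch(read_eem(st$spectra$eem),
               error = function(e) note("spectra", conditionMessage(e)))
    }
    if (check_file("spectra", st$spectra$absorption)) {
      tryCatch(read_spectra_table(st$spectra$absorption),
               error = function(e) note("spectra", conditionMessage(e)))
    }
  }
  if (length(fails)) list_rbind(fails) else tibble(stage = character(0),
                                                  problem = character(0))
}

#' Run the antenna dissection pipeline
#'
#' Executes the requested stages in dependency order (sequences,
#' chromatogram, spectra, geometry, em), writing per-stage tables, a
#' combined JSON report and a log (package version, seeds, timings) into
#' the output directory. Reruns with the same config and seed produce
#' identical primary outputs. A stage failure aborts with the stage named;
#' outputs of earlier stages are retained.
#'
#' @param config a `run_config` (see [read_run_config()] /
#'   [as_run_config()]).
#' @param out output directory (overrides `config$out`).
#' @return the run report (named list), invisibly written to
#'   `report.json`.
#' @export
run_pipeline <- function(config, out = NULL) {
  config <- if (inherits(config, "run_config")) config else as_run_config(config)
  out <- out %||% config$out %||% abort("no output directory configured")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out, "config_echo.yaml"))
  log_lines <- c(sprintf("phycoantenna %s",
                         as.character(utils::packageVersion("phycoantenna"))),
                 sprintf("root seed: %d", config$seed))
  report <- list(seed = config$seed)
  st <- config$stages
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage %s: %s", name,
                                      conditionMessage(e))),
                 file.path(out, "run.log"))
      abort(sprintf("pipeline failed at stage '%s': %s", name,
                    conditionMessage(e)))
    })
  }

  if (!is.null(st$sequences)) {
    report$sequences <- run_stage("sequences", function() {
      sim <- st$sequences$simulate
      cand <- if (!is.null(sim)) {
        do.call(gen_alpha_sequences,
                modifyList(sim, list(seed = child_seed(config$seed, "seq"))))$candidates
      } else read_alpha_fasta(st$sequences$fasta)
      cat_tbl <- catalog_alpha_subunits(cand)
      write_alpha_catalog(cat_tbl, file.path(out, "alpha_catalog.tsv"),
                          file.path(out, "mature_alpha.fasta"))
      list(n_candidates = nrow(cand), n_mature = nrow(cat_tbl),
           form_counts = as.list(table(cat_tbl$form_class)))
    })
    log_lines <- c(log_lines, "stage sequences: ok")
  }

  if (!is.null(st$chromatogram)) {
    report$chromatogram <- run_stage("chromatogram", function() {
      sim <- st$chromatogram$simulate
      if (!is.null(sim)) {
        gen <- do.call(gen_chromatogram,
                       modifyList(sim, list(seed = child_seed(config$seed, "chrom"))))
        pink <- gen$pink; purple <- gen$purple; peaks <- gen$named_peaks
      } else {
        pink <- read_chromatogram(st$chromatogram$pink)
        purple <- read_chromatogram(st$chromatogram$purple)
        peaks <- readr::read_tsv(st$chromatogram$peaks, show_col_types = FALSE)
      }
      if (isTRUE(st$chromatogram$rescue_saturation %||% TRUE)) {
        pink <- rescale_saturated_channel(pink)
        purple <- rescale_saturated_channel(purple)
      }
      ab <- spectrotype_fractions(pink, purple, peaks)
      write_abundance_table(ab, file.path(out, "abundances.tsv"),
                            file.path(out, "abundances.json"))
      list(peaks = as_tibble(ab)[, c("peak", "fraction", "spectrotype", "frac")],
           residual_fraction = attr(ab, "residual_fraction"),
           spectrotypes = attr(ab, "spectrotypes"))
    })
    log_lines <- c(log_lines, "stage chromatogram: ok")
  }

  if (!is.null(st$spectra)) {
    report$spectra <- run_stage("spectra", function() {
      sim <- st$spectra$simulate
      out_sp <- list()
      if (!is.null(sim$absorption)) {
        g <- gen_absorption_spectrum(
          bands = as_tibble(sim$absorption$bands),
          noise_sd = sim$absorption$noise_sd %||% 0,
          seed = child_seed(config$seed, "abs"))
        pks <- find_peaks(normalize_spectrum(g$spectrum, "unit_max"),
                          min_prominence = 0.05)
        out_sp$absorption_peaks <- pks
      } else if (!is.null(st$spectra$absorption)) {
        sp <- read_spectra_table(st$spectra$absorption)
        out_sp$absorption_peaks <- list_rbind(imap(sp, function(s, nm) {
          mutate(find_peaks(s), spectrum = nm)
        }))
      }
      eem <- NULL
      if (!is.null(sim$eem)) {
        g <- gen_eem(components = as_tibble(sim$eem$components),
                     rayleigh = sim$eem$rayleigh,
                     noise_sd = sim$eem$noise_sd %||% 0,
                     seed = child_seed(config$seed, "eem"))
        eem <- g$eem
      } else if (!is.null(st$spectra$eem)) {
        eem <- read_eem(st$spectra$eem)
      }
      if (!is.null(eem)) {
        em <- eem_to_emission(eem)
        rr <- remove_rayleigh(em)
        emn <- normalize_spectrum(rr$spectrum, "unit_max")
        out_sp$emission_peaks <- find_peaks(emn, min_prominence = 0.05)
        out_sp$rayleigh <- rr$model[c("c", "n")]
      }
      if (!is.null(out_sp$absorption_peaks)) {
        readr::write_tsv(out_sp$absorption_peaks,
                         file.path(out, "absorption_peaks.tsv"))
      }
      if (!is.null(out_sp$emission_peaks)) {
        readr::write_tsv(out_sp$emission_peaks,
                         file.path(out, "emission_peaks.tsv"))
      }
      out_sp
    })
    log_lines <- c(log_lines, "stage spectra: ok")
  }

  if (!is.null(st$geometry)) {
    report$geometry <- run_stage("geometry", function() {
      sim <- st$geometry$simulate
      if (!is.null(sim)) {
        ids <- sim$identities %||% c("PEB", "PCB", "DBV")
        reports <- list_rbind(imap(setNames(ids, ids), function(idn, nm) {
          g <- gen_bilin_coords(idn, noise_sd = sim$noise_sd %||% 0,
                                seed = child_seed(config$seed, paste0("bilin", nm)))
          mutate(bilin_geometry_report(g$bilin), truth = idn)
        }))
      } else {
        atoms <- read_structure(st$geometry$structure)
        chrom <- as_tibble(st$geometry$chromophores)
        reports <- list_rbind(map(seq_len(nrow(chrom)), function(i) {
          b <- extract_bilin(atoms, chrom$chain[i], chrom$resid[i])
          bilin_geometry_report(b)
        }))
      }
      readr::write_tsv(reports, file.path(out, "chromophore_geometry.tsv"))
      reports
    })
    log_lines <- c(log_lines, "stage geometry: ok")
  }

  if (!is.null(st$em)) {
    report$em <- run_stage("em", function() {
      sim <- st$em$simulate
      if (!is.null(sim)) {
        g <- do.call(gen_striation_image,
                     modifyList(sim, list(seed = child_seed(config$seed, "em"))))
        img <- g$image; scale <- g$scale
      } else {
        img <- read_micrograph(st$em$image)
        scale <- st$em$scale
      }
      mask <- detect_edges(img)
      sp <- striation_spacings(mask, scale)
      readr::write_tsv(tibble(distance_nm = sp$distances),
                       file.path(out, "striation_distances.tsv"))
      list(mean_nm = sp$mean, sd_nm = sp$sd, n = length(sp$distances))
    })
    log_lines <- c(log_lines, "stage em: ok")
  }

  writeLines(log_lines, file.path(out, "run.log"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
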