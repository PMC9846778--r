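#' Extraction-scenario presets
#'
#' The five simulation scenarios used to probe de novo extraction. Scenarios
#' 1-3 reference named COSMIC signatures (scenario 1 is the six-member flat
#' cluster, of which SBS3, SBS5, SBS40 and SBS92 are named in the main
#' analysis — the remaining members are resolved from the cluster map of the
#' user's catalogue at the `similarity_cut`; scenario 2 is the polymerase /
#' ROS cluster; scenario 3 their union). Scenarios 4 and 5 select 11 and 20
#' low-flatness signatures, each required to have at least one partner at
#' cosine similarity above the cut. All presets therefore require a
#' user-supplied COSMIC signature file and fail with a clear message when
#' the referenced signatures are absent.
#'
#' @param id Scenario number, 1-5.
#' @return A list describing the preset: `id`, `named_signatures`,
#'   `resolve` (how to complete the set from a catalogue: `"flat_cluster"`,
#'   `"named"`, `"union"`, `"low_flatness_paired"`), `n_signatures`,
#'   `n_samples_grid`, `similarity_cut`.
#' @export
scenario_preset <- function(id) {
  presets <- list(
    list(id = 1L, named_signatures = c("SBS3", "SBS5", "SBS40", "SBS92"),
         resolve = "flat_cluster", n_signatures = 6L,
         n_samples_grid = c(200L, 500L), similarity_cut = 0.8),
    list(id = 2L, named_signatures = c("SBS10a", "SBS10c", "SBS10d", "SBS18", "SBS36"),
         resolve = "named", n_signatures = 5L,
         n_samples_grid = c(200L, 500L), similarity_cut = 0.8),
    list(id = 3L, named_signatures = character(0), resolve = "union",
         n_signatures = 11L,
         n_samples_grid = c(200L, 500L, 1000L, 3000L, 5000L, 10000L),
         similarity_cut = 0.8),
    list(id = 4L, named_signatures = character(0), resolve = "low_flatness_paired",
         n_signatures = 11L,
         n_samples_grid = c(200L, 500L, 1000L, 3000L, 5000L),
         similarity_cut = 0.8),
    list(id = 5L, named_signatures = character(0), resolve = "low_flatness_paired",
         n_signatures = 20L,
         n_samples_grid = c(1000L, 3000L, 5000L, 10000L),
         similarity_cut = 0.8)
  )
  if (!id %in% 1:5) stop("scenario id must be 1-5")
  presets[[id]]
}

#' Resolve a scenario preset against a signature catalogue
#'
#' @param sig A [signature_matrix()] (typically the artefact-filtered COSMIC
#'   catalogue).
#' @param preset A preset from [scenario_preset()].
#' @return A [signature_matrix()] of the scenario's generating signatures.
#' @export
resolve_scenario_signatures <- function(sig, preset) {
  stopifnot(inherits(sig, "signature_matrix"))
  need <- if (preset$resolve == "union") {
    union(scenario_preset(1L)$named_signatures, scenario_preset(2L)$named_signatures)
  } else {
    preset$named_signatures
  }
  missing <- setdiff(need, rownames(sig))
  if (length(missing) > 0L) {
    stop("scenario ", preset$id, " references signatures absent from the ",
         "supplied catalogue: ", paste(missing, collapse = ", "),
         ". Supply a COSMIC v3.3-style signature file containing them.")
  }
  pick <- switch(preset$resolve,
    named = need,
    flat_cluster = ,
    union = {
      groups <- cut_cluster_map(build_cluster_map(pairwise_similarity(sig)),
                                similarity_cut = preset$similarity_cut)
      anchor_groups <- unique(groups$group[groups$signature %in% need])
      members <- groups$signature[groups$group %in% anchor_groups]
      union(need, members)
    },
    low_flatness_paired = {
      groups <- cut_cluster_map(build_cluster_map(pairwise_similarity(sig)),
                                similarity_cut = preset$similarity_cut)
      paired <- groups |>
        dplyr::add_count(.data$group) |>
        dplyr::filter(.data$n >= 2L)
      fl <- signature_flatness(sig) |>
        dplyr::filter(.data$signature %in% paired$signature) |>
        dplyr::arrange(.data$flatness)
      utils::head(fl$signature, preset$n_signatures)
    }
  )
  if (length(pick) < preset$n_signatures) {
    stop("scenario ", preset$id, " could not assemble ", preset$n_signatures,
         " signatures from the supplied catalogue (got ", length(pick), ")")
  }
  keep <- rownames(sig) %in% pick
  signature_matrix(as_plain(sig)[keep, , drop = FALSE])
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage seed expansion, kept within 32-bit range
  offs <- c(metrics = 101L, simulate = 211L, extract = 307L,
            evaluate = 401L, archetypes = 503L)
  (as.integer(seed) + offs[[stage]] * 1009L) %% 2147483647L
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages — similarity/flatness metrics, catalogue
#' simulation, de novo extraction, scenario evaluation, archetypal analysis
#' — over one signature set, writing every artifact plus a run manifest
#' (config snapshot, derived seeds, stage timings, output inventory with
#' MD5 checksums) to the output directory. Deterministic stages re-run
#' bit-identically from the manifest's config and seed.
#'
#' @param config A list:
#' \describe{
#'   \item{signatures}{path to a COSMIC-dialect TSV, a
#'     [signature_matrix()], or a list spec for
#'     [generate_synthetic_signatures()] (fields `k`, `target_flatness`,
#'     optional `max_pairwise_sim`, `n_active`).}
#'   \item{stages}{subset of `c("metrics", "simulate", "extract",
#'     "evaluate", "archetypes")`.}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{integer master seed, expanded per stage.}
#'   \item{n_samples, mutations_per_sample, n_replicates}{simulation
#'     settings (defaults 100, 5000, 2).}
#'   \item{k_range, n_runs, threshold}{extractor settings.}
#'   \item{r_range, restarts, ev_threshold}{archetype settings.}
#' }
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
pipeline_run <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  stages <- config$stages %||% c("metrics", "simulate", "extract", "evaluate", "archetypes")
  seed <- as.integer(config$seed %||% 1L)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  sig <- config$signatures
  if (is.character(sig)) sig <- read_signature_table(sig)
  if (is.list(sig) && !inherits(sig, "signature_matrix")) {
    sig <- generate_synthetic_signatures(
      k = sig$k, target_flatness = sig$target_flatness %||% 0.4,
      max_pairwise_sim = sig$max_pairwise_sim,
      n_active = sig$n_active %||% 4L, seed = stage_seed(seed, "simulate")
    )
  }
  stopifnot(inherits(sig, "signature_matrix"))

  manifest <- list(config = config[setdiff(names(config), "signatures")],
                   seed = seed, seeds = list(),
                   package_version = as.character(utils::packageVersion("sigarchetypes")),
                   timings = list(), outputs = character(0))
  emit <- function(path) manifest$outputs <<- c(manifest$outputs, path)
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    on.exit(manifest$timings[[stage]] <<-
              as.numeric(difftime(Sys.time(), t0, units = "secs")), add = TRUE)
    force(expr)
  }

  write_signature_table(sig, file.path(out, "signatures.tsv"))
  emit(file.path(out, "signatures.tsv"))

  scen <- NULL
  failed <- character(0)
  for (stage in stages) {
    manifest$seeds[[stage]] <- stage_seed(seed, stage)
    ok <- tryCatch({
      timed(stage, switch(stage,
        metrics = {
          simm <- pairwise_similarity(sig)
          ord <- build_cluster_map(simm)$leaf_order
          readr::write_tsv(tibble::as_tibble(simm$sim[ord, ord], rownames = "signature"),
                           file.path(out, "similarity.tsv"), progress = FALSE)
          cluster_map_newick(build_cluster_map(simm), file.path(out, "cluster_map.nwk"))
          readr::write_tsv(signature_flatness(sig),
                           file.path(out, "flatness.tsv"), progress = FALSE)
          readr::write_tsv(scenario_summary(sig),
                           file.path(out, "scenario_summary.tsv"), progress = FALSE)
          emit(file.path(out, c("similarity.tsv", "cluster_map.nwk",
                                "flatness.tsv", "scenario_summary.tsv")))
        },
        simulate = {
          cfg <- scenario_config(
            n_samples = config$n_samples %||% 100L,
            mutations_per_sample = config$mutations_per_sample %||% 5000L,
            n_replicates = config$n_replicates %||% 2L,
            seed = stage_seed(seed, "simulate"))
          scen <- generate_scenario(sig, cfg)
          for (r in seq_along(scen)) {
            p <- file.path(out, sprintf("catalogue_rep%02d.tsv", r))
            write_catalogue(scen[[r]]$catalogue, p)
            emit(p)
          }
        },
        extract = {
          if (is.null(scen)) stop("extract stage requires the simulate stage")
          res <- extract_signatures(
            scen[[1L]]$catalogue,
            k_range = config$k_range %||% seq_len(min(nrow(sig) + 2L, 8L)),
            n_runs = config$n_runs %||% 5L,
            seed = stage_seed(seed, "extract"))
          write_signature_table(res$signatures, file.path(out, "consensus_signatures.tsv"))
          readr::write_tsv(tibble::as_tibble(res$exposures, rownames = "signature"),
                           file.path(out, "exposures.tsv"), progress = FALSE)
          jsonlite::write_json(tidy(res$selection), file.path(out, "extraction_diagnostics.json"),
                               auto_unbox = TRUE, digits = NA)
          emit(file.path(out, c("consensus_signatures.tsv", "exposures.tsv",
                                "extraction_diagnostics.json")))
        },
        evaluate = {
          if (is.null(scen)) stop("evaluate stage requires the simulate stage")
          ev <- evaluate_scenario(
            scen,
            k_range = config$k_range %||% seq_len(min(nrow(sig) + 2L, 8L)),
            threshold = config$threshold %||% 0.8,
            n_runs = config$n_runs %||% 5L,
            seed = stage_seed(seed, "evaluate"))
          jsonlite::write_json(list(F = ev$F, mse = as.list(ev$mse),
                                    stability = as.list(ev$stability),
                                    per_replicate = ev$per_replicate),
                               file.path(out, "evaluation.json"),
                               auto_unbox = TRUE, digits = NA)
          emit(file.path(out, "evaluation.json"))
        },
        archetypes = {
          r_range <- config$r_range %||% seq_len(min(nrow(sig), 6L))
          curve <- explained_variance_curve(sig, r_range,
                                            restarts = config$restarts %||% 3L,
                                            seed = stage_seed(seed, "archetypes"))
          selected <- select_num_archetypes(curve, config$ev_threshold %||% 0.95)
          model <- attr(curve, "models")[[as.character(selected$r)]]
          report <- reconstruction_report(model, sig)
          write_signature_table(signature_matrix(model$Z), file.path(out, "archetypes.tsv"))
          readr::write_tsv(tibble::as_tibble(model$alpha, rownames = "signature"),
                           file.path(out, "alpha.tsv"), progress = FALSE)
          jsonlite::write_json(
            list(r = selected$r, reached = selected$reached,
                 explained_variance = model$explained_variance,
                 ev_curve = tibble::as_tibble(curve),
                 per_signature = report$per_signature,
                 per_archetype = report$per_archetype,
                 groups = alpha_grouping(model)$groups),
            file.path(out, "archetypes.json"), auto_unbox = TRUE, digits = NA)
          emit(file.path(out, c("archetypes.tsv", "alpha.tsv", "archetypes.json")))
        }
      ))
      TRUE
    }, error = function(e) {
      warning("stage '", stage, "' failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) failed <- c(failed, stage)
  }

  manifest$failed_stages <- failed
  manifest$complete <- length(failed) == 0L
  manifest$checksums <- as.list(tools::md5sum(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(manifest, class = "run_manifest")
}

#' Summary tables from a pipeline run
#'
#' Rebuilds the scenario-description table (number of signatures, median
#' similarity, median flatness, samples) and the extraction-performance
#' table (F, MSE median with IQR, C_mean, C_min) from a run's artifacts.
#'
#' @param manifest A `run_manifest` from [pipeline_run()], or the path to a
#'   run's `manifest.json`.
#' @return List of tibbles `scenario` and `performance`.
#' @export
report_tables <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  outs <- unlist(manifest$outputs)
  need <- function(pattern, stage) {
    hit <- grep(pattern, outs, value = TRUE)
    if (length(hit) == 0L || !file.exists(hit[1L])) {
      stop("missing output of stage '", stage, "' (", pattern, "); run it first")
    }
    hit[1L]
  }
  summ <- readr::read_tsv(need("scenario_summary\\.tsv$", "metrics"),
                          show_col_types = FALSE, progress = FALSE)
  ev <- jsonlite::read_json(need("evaluation\\.json$", "evaluate"))
  n_samples <- manifest$config$n_samples %||% NA_integer_
  scenario <- tibble::tibble(
    n_signatures = summ$n_signatures,
    median_similarity = summ$median_similarity,
    median_flatness = summ$median_flatness,
    n_samples = as.integer(n_samples)
  )
  performance <- tibble::tibble(
    n_samples = as.integer(n_samples),
    F = ev$F,
    mse = sprintf("%.2f (%.2f-%.2f)", ev$mse$median, ev$mse$q1, ev$mse$q3),
    C_mean = ev$stability$C_mean,
    C_min = ev$stability$C_min
  )
  list(scenario = scenario, performance = performance)
}
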