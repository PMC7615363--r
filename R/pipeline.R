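#' Pipeline configuration
#'
#' Bundles everything one end-to-end analysis needs: a seed, either a
#' simulation campaign or per-round input FASTA paths, stage toggles and
#' stage parameters. Serialized (with its RNG seed) next to the outputs for
#' full provenance.
#'
#' @param seed A [seed_construct()].
#' @param campaign A [campaign_config()] (simulate the pools), or `NULL`
#'   when `input_fastas` is given.
#' @param input_fastas Named character vector of per-round FASTA paths,
#'   names like `"R0"`, `"R1"`, strictly increasing rounds.
#' @param stages Character vector of stages to run, from
#'   `c("diversity", "mutation", "motifs", "structure", "embedding")`.
#' @param motif Pattern or descriptor for the motif stage.
#' @param trim Trim primers off input pools before the diversity/mutation
#'   stages (`max_mismatch` 0).
#' @param fold_engine `"fallback"` or `"external"` for the structure stage.
#' @param pad_len Padded length for the embedding stage.
#' @param rng_seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(seed, campaign = NULL, input_fastas = NULL,
                            stages = c("diversity", "mutation", "motifs",
                                       "structure", "embedding"),
                            motif = "GGNAGANNNTG", trim = TRUE,
                            fold_engine = "fallback", pad_len = 80,
                            rng_seed = 1, out_dir = NULL) {
  stopifnot(inherits(seed, "seed_construct"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(campaign) && is.null(input_fastas)) {
    abort("either a campaign or input_fastas must be given")
  }
  if (!is.null(input_fastas)) {
    rounds <- as.integer(sub("^R", "", names(input_fastas)))
    if (anyNA(rounds) || any(diff(rounds) <= 0)) {
      abort("input_fastas must be named R0, R1, ... with strictly increasing rounds")
    }
  }
  structure(list(seed = seed, campaign = campaign,
                 input_fastas = input_fastas, stages = stages, motif = motif,
                 trim = trim, fold_engine = fold_engine, pad_len = pad_len,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with keys mirroring the [pipeline_config()] arguments;
#' `seed:` holds `name`/`fwd_primer`/`core`/`rev_primer`, `campaign:` the
#' [campaign_config()] scalars (replication and selection parameter
#' overrides under `replication:` / `selection:`).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort("config must define a seed")
  seed <- seed_construct(y$seed$name, y$seed$fwd_primer, y$seed$core,
                         y$seed$rev_primer)
  campaign <- NULL
  if (!is.null(y$campaign)) {
    rp <- do.call(replication_params, y$campaign$replication %||% list())
    sp <- do.call(selection_params, y$campaign$selection %||% list())
    campaign <- campaign_config(
      seed, n_rounds = y$campaign$n_rounds %||% 8, replication = rp,
      selection = sp,
      molecules_per_round = y$campaign$molecules_per_round %||% 2000,
      rng_seed = y$campaign$rng_seed %||% y$rng_seed %||% 1)
  }
  args <- y[intersect(names(y), c("stages", "motif", "trim", "fold_engine",
                                  "pad_len", "rng_seed", "out_dir"))]
  fastas <- unlist(y$input_fastas)
  do.call(pipeline_config,
          c(list(seed = seed, campaign = campaign,
                 input_fastas = fastas), args))
}

pipeline_stage <- function(name, config, fn) {
  if (!name %in% config$stages) return(list(status = "skipped"))
  tryCatch(c(list(status = "ok"), fn()),
           error = function(e) {
             abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
           })
}

#' Run the full round-by-round analysis pipeline
#'
#' Simulates (or ingests) the per-round pools, then runs the enabled
#' stages: Damerau-Levenshtein distance summaries to the seed, per-position
#' mutation rates over the core, motif frequencies, folding-energy medians
#' and the shared 2-D embedding. Deterministic given the configuration's
#' RNG seed. When `out_dir` is set, each stage table is written as TSV, the
#' report as JSON, and the configuration (with a content hash) alongside.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list with `pools`, one element per stage
#'   (each a tibble or `"skipped"`), and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$rng_seed)
  seed <- config$seed
  pools <- if (!is.null(config$campaign)) {
    run_campaign(config$campaign)
  } else {
    purrr::imap(as.list(config$input_fastas), function(p, nm) {
      read_pool(p, round = as.integer(sub("^R", "", nm)),
                seed_name = seed$name)
    })
  }
  pools <- lapply(pools, collapse_pool)
  inserts <- lapply(pools, function(p) {
    if (config$trim) trim_primers(p, seed, max_mismatch = 0) else p
  })
  rounds <- vapply(pools, pool_round, 0L)

  diversity <- pipeline_stage("diversity", config, function() {
    tab <- purrr::map_dfr(pools, function(p) {
      if (nrow(p) == 0) return(NULL)
      g <- glance(pool_distance_distribution(p, seed))
      mutate(g, round = pool_round(p), .before = 1)
    })
    list(table = tab)
  })
  mutation <- pipeline_stage("mutation", config, function() {
    tab <- purrr::map_dfr(inserts, function(p) {
      if (nrow(p) == 0) return(NULL)
      prof <- positionwise_mutation_rate(p, seed)
      tibble(round = pool_round(p), mean_rate = mean_mutation_rate(prof),
             covered_positions = sum(prof$total > 0))
    })
    list(table = tab)
  })
  motifs <- pipeline_stage("motifs", config, function() {
    list(table = motif_frequency_by_round(pools, config$motif))
  })
  structure_stage <- pipeline_stage("structure", config, function() {
    tab <- purrr::map_dfr(pools, function(p) {
      if (nrow(p) == 0) return(NULL)
      g <- glance(pool_energy_distribution(p, engine = config$fold_engine))
      mutate(g, round = pool_round(p), .before = 1)
    })
    list(table = tab)
  })
  embedding <- pipeline_stage("embedding", config, function() {
    # rare recombinants can exceed the pad length; they are excluded from
    # the embedding (and counted) rather than aborting the stage
    trimmed <- lapply(pools, function(p) {
      restamp(as_tibble(p)[nchar(p$sequence) <= config$pad_len, ], p)
    })
    n_excl <- sum(vapply(pools, nrow, 0L)) - sum(vapply(trimmed, nrow, 0L))
    nonempty <- trimmed[vapply(trimmed, nrow, 0L) > 0]
    list(coords = embed_rounds(nonempty, pad_len = config$pad_len,
                               markers = c(seed = seed_sequence(seed))),
         n_excluded_too_long = n_excl)
  })

  provenance <- list(
    seed = seed$name, rng_seed = config$rng_seed, stages = config$stages,
    rounds = rounds,
    reads_per_round = vapply(pools, total_reads, 0L),
    unique_per_round = vapply(pools, unique_count, 0L),
    config_hash = config_hash(config))
  report <- structure(
    list(pools = pools, diversity = diversity, mutation = mutation,
         motifs = motifs, structure = structure_stage,
         embedding = embedding, provenance = provenance),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

config_hash <- function(config) {
  # stable content hash of the serialized config (no external digest dep)
  txt <- paste(deparse(unclass(config)[setdiff(names(config), "out_dir")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in c("diversity", "mutation", "motifs", "structure")) {
    st <- report[[stage]]
    if (!identical(st$status, "ok")) next
    utils::write.table(st$table, file.path(out_dir, paste0(stage, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (identical(report$embedding$status, "ok")) {
    utils::write.table(as_tibble(report$embedding$coords),
                       file.path(out_dir, "embedding.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    c(report$provenance,
      list(stage_status = lapply(
        report[c("diversity", "mutation", "motifs", "structure",
                 "embedding")], `[[`, "status"))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  rounds: %s\n", paste(x$provenance$rounds, collapse = ", ")))
  for (stage in c("diversity", "mutation", "motifs", "structure",
                  "embedding")) {
    cat(sprintf("  %-10s %s\n", stage, x[[stage]]$status))
  }
  invisible(x)
}
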