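#' Configuration for a single-domain analysis
#'
#' Collects every tunable of the pipeline with the defaults of record:
#' 10 angstrom contact cutoff, the seven slowest modes, 15-residue minimum
#' DE length, the three threshold presets (3,8), (5,10), (5,15), and a null
#' of 1000 random sets of 30 segments of 30-175 residues validated under
#' the (3,8) preset.
#'
#' @param structure_path,chain_id,range PDB input for [read_domain()], or
#'   `NULL` when `domain` is given directly to [run_domain_analysis()].
#' @param themes_path Theme TSV for [read_themes()], or `NULL` to stop after
#'   the DE stage.
#' @param rc Contact cutoff (angstrom).
#' @param n_modes Number of slowest modes analyzed.
#' @param min_len Minimum DE length (residues).
#' @param presets List of `c(max_overlap, max_gap)` threshold pairs.
#' @param n_null,null_size,null_len_range Null-set count, segments per set,
#'   and segment length range.
#' @param null_preset Threshold pair used for null validity and scoring.
#' @param cap Combination-enumeration cap.
#' @param seed Master seed for the null generation.
#' @param theme_min_len Minimum theme length accepted by the loader.
#' @return A `run_config` list.
#' @export
run_config <- function(structure_path = NULL, chain_id = "A", range = "all",
                       themes_path = NULL, rc = 10, n_modes = 7L,
                       min_len = 15L,
                       presets = list(c(3L, 8L), c(5L, 10L), c(5L, 15L)),
                       n_null = 1000L, null_size = 30L,
                       null_len_range = c(30L, 175L),
                       null_preset = c(3L, 8L),
                       cap = 1e5, seed = 1L, theme_min_len = 35L) {
  structure(list(structure_path = structure_path, chain_id = chain_id,
                 range = range, themes_path = themes_path, rc = rc,
                 n_modes = n_modes, min_len = min_len, presets = presets,
                 n_null = n_null, null_size = null_size,
                 null_len_range = null_len_range, null_preset = null_preset,
                 cap = cap, seed = seed, theme_min_len = theme_min_len),
            class = "run_config")
}

#' Run the full theme-dynamics analysis for one domain
#'
#' Executes structure reading, mode computation, DE segmentation, theme
#' loading, combination enumeration and AMI/SMI scoring per threshold preset,
#' and the Monte-Carlo p-value analysis, writing all result tables as TSV
#' plus a JSON manifest into `out_dir`. Given the same configuration and
#' seed, the outputs are identical between runs. If no themes are supplied
#' the run stops after the DE stage (DE outputs are still written).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param domain Optionally, a `dyn_domain` tibble used instead of reading
#'   `config$structure_path`.
#' @param themes Optionally, a validated theme tibble used instead of reading
#'   `config$themes_path`.
#' @return Invisibly, a list with every intermediate result (`domain`,
#'   `modes`, `elements`, `themes`, `summaries`, `pvalues`, `manifest`).
#' @export
run_domain_analysis <- function(config, out_dir, domain = NULL, themes = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", what, "' failed: ", conditionMessage(e)))
    })
  }

  domain <- stage("structure_io", {
    if (is.null(domain)) {
      if (is.null(config$structure_path)) abort("no structure input")
      read_domain(config$structure_path, config$chain_id, config$range)
    } else domain
  })
  n <- nrow(domain)
  readr::write_tsv(domain_map(domain), file.path(out_dir, "residue_map.tsv"))

  modes <- stage("gnm", gnm_modes(domain, rc = config$rc))
  readr::write_tsv(tidy(modes), file.path(out_dir, "eigenvalues.tsv"))
  readr::write_tsv(sense_profile(modes, seq_len(config$n_modes)),
                   file.path(out_dir, "senses.tsv"))

  elements <- stage("dynamic_elements",
                    dynamic_elements(modes, seq_len(config$n_modes),
                                     min_len = config$min_len))
  de_track <- dplyr::mutate(elements, domain_id = domain_id(domain),
                            .before = 1L)
  readr::write_tsv(de_track, file.path(out_dir, "de_track.tsv"))

  if (is.null(themes) && is.null(config$themes_path)) {
    inform("no themes supplied; stopping after the DE stage")
    manifest <- run_manifest(config, domain, themes_used = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(domain = domain, modes = modes,
                          elements = elements, manifest = manifest)))
  }

  themes <- stage("themes", {
    if (is.null(themes)) {
      read_themes(config$themes_path, n, min_len = config$theme_min_len)
    } else themes
  })
  parts_de <- de_partitions(elements, seq_len(config$n_modes))

  summaries <- stage("mi_stats", purrr::map_dfr(config$presets, function(p) {
    cb <- enumerate_combinations(themes, n, p[1], p[2], cap = config$cap)
    if (nrow(cb) == 0L) {
      warn(paste0("no valid combination under preset (", p[1], ",", p[2], ")"))
      return(tibble())
    }
    pt <- combination_partitions(cb, themes, n)
    mode_theme_summary(score_combinations(parts_de, pt)) |>
      dplyr::mutate(max_overlap = p[1], max_gap = p[2], .before = 1L)
  }))
  readr::write_tsv(summaries, file.path(out_dir, "ami_smi_summary.tsv"))

  pvalues <- stage("significance", with_seed(config$seed, {
    np <- config$null_preset
    cb <- enumerate_combinations(themes, n, np[1], np[2], cap = config$cap)
    if (nrow(cb) == 0L) abort("no valid real combination under null preset")
    pt <- combination_partitions(cb, themes, n)
    sets <- valid_random_sets(n, count = config$n_null,
                              size = config$null_size,
                              len_range = config$null_len_range,
                              max_overlap = np[1], max_gap = np[2])
    mode_pvalues(parts_de, pt, sets, n, np[1], np[2], cap = config$cap) |>
      dplyr::mutate(domain_id = domain_id(domain), seed = config$seed,
                    .before = 1L)
  }))
  readr::write_tsv(pvalues, file.path(out_dir, "pvalues.tsv"))

  manifest <- run_manifest(config, domain, themes_used = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(domain = domain, modes = modes, elements = elements,
                 themes = themes, summaries = summaries, pvalues = pvalues,
                 manifest = manifest))
}

run_manifest <- function(config, domain, themes_used) {
  cfg <- unclass(config)
  cfg$presets <- lapply(cfg$presets, as.integer)
  list(
    package = "themedyn",
    version = as.character(utils::packageVersion("themedyn")),
    domain_id = domain_id(domain),
    n_residues = nrow(domain),
    themes_used = themes_used,
    config = cfg,
    config_hash = rlang::hash(cfg)
  )
}
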