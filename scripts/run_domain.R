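#!/usr/bin/env Rscript
# Thin command-line wrapper over themedyn::run_domain_analysis() for one
# domain. Example:
#   Rscript scripts/run_domain.R --pdb dom.pdb --chain A --themes themes.tsv \
#       --out results/dom --seed 1

suppressMessages(library(themedyn))
suppressMessages(library(optparse))

opts <- parse_args(OptionParser(option_list = list(
  make_option("--pdb", type = "character", help = "PDB file"),
  make_option("--chain", type = "character", default = "A"),
  make_option("--from", type = "integer", default = NA_integer_,
              help = "author-number range start (default: whole chain)"),
  make_option("--to", type = "integer", default = NA_integer_),
  make_option("--themes", type = "character", default = NULL,
              help = "theme TSV (theme_id, variation, start, end); omit to stop after the DE stage"),
  make_option("--rc", type = "double", default = 10),
  make_option("--n-modes", type = "integer", default = 7L, dest = "n_modes"),
  make_option("--min-len", type = "integer", default = 15L, dest = "min_len"),
  make_option("--n-null", type = "integer", default = 1000L, dest = "n_null"),
  make_option("--cap", type = "double", default = 1e5),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/domain")
)))

range <- if (is.na(opts$from)) "all" else c(opts$from, opts$to)
cfg <- run_config(structure_path = opts$pdb, chain_id = opts$chain,
                  range = range, themes_path = opts$themes, rc = opts$rc,
                  n_modes = opts$n_modes, min_len = opts$min_len,
                  n_null = opts$n_null, cap = opts$cap, seed = opts$seed)
run_domain_analysis(cfg, opts$out)
cat("results written to", opts$out, "\n")
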