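#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's experiment runner.
#
#   Rscript scripts/arena.R <experiment> [--mode polyandry|outcrossing]
#                           [--seed N] [--out DIR] [--simulate]
#                           [--numerical] [--paper-scale]
#   Rscript scripts/arena.R validate [--seed N]
#
# Experiments: load_sweep, polyandry_surface, depression_sweep,
# balancing_sweep, modifier_sweep, depression_sigma_sweep, invasion_check.

suppressPackageStartupMessages({
  library(gameticsel)
  library(optparse)
})

parser <- OptionParser(
  usage = "usage: Rscript scripts/arena.R <experiment|validate> [options]",
  option_list = list(
    make_option("--mode", default = "polyandry",
                help = "mating-system axis [default %default]"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", default = NULL,
                help = "output directory for TSV/JSON/plots"),
    make_option("--simulate", action = "store_true", default = FALSE,
                help = "add individual-based simulation points"),
    make_option("--numerical", action = "store_true", default = FALSE,
                help = "verify invasion_check with the exact engine"),
    make_option("--paper-scale", action = "store_true", default = FALSE,
                dest = "paper_scale",
                help = "full-scale simulations (N=5000, L=100, 50k gens)")
  )
)
parsed <- parse_args(parser, positional_arguments = 1L)
verb <- parsed$args
o <- parsed$options

if (verb == "validate") {
  res <- validate_predictions(seed = o$seed)
  print.data.frame(as.data.frame(res), digits = 6)
  quit(status = if (all(res$pass)) 0L else 1L)
}

ex <- run_experiment(verb, mode = o$mode, simulate = o$simulate,
                     numerical = o$numerical,
                     scale = if (o$paper_scale) "paper" else "desk",
                     seed = o$seed, out_dir = o$out)
print(ex)
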