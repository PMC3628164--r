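#!/usr/bin/env Rscript

## Thin command-line wrapper over the hbcmap pipeline functions.
##
## Usage:
##   Rscript scripts/pipeline.R <simulate|fit-predict|estimate|validate|report|all>
##       [--config scenario.yaml] [--out out_dir]
##
## Stages after `simulate` read that stage's outputs from --out, so the
## subcommands can be run one at a time or all at once with `all`.

suppressPackageStartupMessages({
  library(optparse)
  library(hbcmap)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L) {
  cat("error code=usage msg=missing subcommand (simulate|fit-predict|estimate|validate|report|all)\n")
  quit(status = 2)
}
cmd <- argv[1]
opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "pipeline-out"))),
  args = argv[-1])

scenario <- if (is.null(opts$config)) {
  default_scenario()
} else {
  load_scenario(opts$config)
}
out <- opts$out

reload_sim <- function() {
  surveys <- load_surveys(file.path(out, "surveys.csv"))
  pop_in <- read_ascii_grid(file.path(out, "population.asc"))
  mask_in <- read_ascii_grid(file.path(out, "country_mask.asc"))
  legend <- readr::read_csv(file.path(out, "country_legend.csv"),
                            show_col_types = FALSE)
  demo <- readr::read_csv(file.path(out, "demographics.csv"),
                          show_col_types = FALSE)
  pop <- structure(list(grid = pop_in$grid, pop = pop_in$values),
                   class = "population_surface")
  units <- matrix(legend$unit_id[mask_in$values], nrow(mask_in$values))
  mask <- structure(list(grid = mask_in$grid, units = units),
                    class = "country_mask")
  list(surveys = surveys, pop = pop, mask = mask, demo = demo)
}

status <- tryCatch({
  switch(cmd,
    "simulate" = run_simulate(scenario, out),
    "fit-predict" = {
      s <- reload_sim()
      run_fit_predict(scenario, s$surveys, out)
    },
    "estimate" = {
      s <- reload_sim()
      fit <- run_fit_predict(scenario, s$surveys, out)
      run_estimate(scenario, fit$field, s$pop, s$mask, s$demo, out)
    },
    "validate" = {
      s <- reload_sim()
      run_validate(scenario, s$surveys, out)
    },
    "all" = run_pipeline(scenario, out),
    "report" = {
      for (f in list.files(out, pattern = "\\.(csv|json)$",
                           full.names = TRUE)) {
        cat("==", basename(f), "==\n")
        cat(readLines(f, n = 12), sep = "\n")
        cat("\n")
      }
      invisible(NULL)
    },
    {
      cat(sprintf("error code=unknown_command msg=%s\n", cmd))
      quit(status = 2)
    })
  0L
}, error = function(e) {
  cat(sprintf("error code=stage_failure msg=%s\n",
              gsub("\n", " ", conditionMessage(e))))
  1L
})
quit(status = status)
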