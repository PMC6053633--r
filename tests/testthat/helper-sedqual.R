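# shared helpers: small delimited fixtures written at test time

write_lines_tmp <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

tiny_fraction_file <- function() {
  write_lines_tmp(c(
    "site,metal,period,F1,F2,F3,F4,F5",
    "QUE,Cd,Jun,1.0,1.0,1.0,0.7,0.68",
    "QUE,Cd,Jul,1.2,1.1,1.0,0.8,0.70",
    "DOU,Pb,Jun,10,10,30,25,25"))
}

# per-metal reciprocal guideline sums for the bundled defaults
default_guideline_sum <- function() {
  g <- default_guidelines()
  setNames(1 / g$tel + 1 / g$pel + 1 / g$sel, g$metal)
}

# printed site ECIs of the case-study survey, used as comparison input
printed_ecis <- c(QUE = 4.06, QUR = 3.80, OKT = 3.46, DOU = 5.06, STB = 3.73)
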