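# Shared fixture builders. Everything is generated in code at test time.

# noise-free logistic series on a day grid
logisticSeries <- function(phi2, phi3, days = seq(105, 145, by = 3)) {
  data.frame(day = days, percent = 100 * plogis(phi2 + phi3 * days))
}

# small RIL population + heading-date architecture used by several files
smallPopulation <- function(nLines = 120, seed = 42) {
  map <- makeGeneticMap(3, 20, 120)
  G <- simulateRILPopulation(map, nLines, seed = seed)
  arch <- traitArchitecture(
    qtl = data.frame(marker = c(10, 30, 50), effect = c(2, 1.5, 1.5)),
    interactions = data.frame(marker1 = 10, marker2 = 50, effect = -1.5),
    polygenicVar = 0.25, intercept = 125)
  list(map = map, G = G, arch = arch,
       hd = geneticValues(G, arch, seed = seed + 1))
}

# balanced single-year plot table with iid noise, known components
balancedPlots <- function(nEntries = 60, r = 2, s2G = 4, s2E = 1,
                          seed = 7) {
  withr::with_seed(seed, {
    g <- rnorm(nEntries, 0, sqrt(s2G))
    tab <- expand.grid(entry = sprintf("E%03d", seq_len(nEntries)),
                       rep = seq_len(r), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    tab$year <- 1
    n <- nrow(tab)
    nc <- ceiling(sqrt(n))
    tab$row <- (seq_len(n) - 1) %/% nc + 1
    tab$col <- (seq_len(n) - 1) %% nc + 1
    tab$value <- 100 + g[match(tab$entry, sprintf("E%03d",
                                                  seq_len(nEntries)))] +
      rnorm(n, 0, sqrt(s2E))
    tab
  })
}

# classical one-way ANOVA expected-mean-squares estimators (balanced)
anovaEMS <- function(tab, r) {
  fit <- stats::aov(value ~ entry, data = tab)
  ms <- summary(fit)[[1]]$`Mean Sq`
  list(s2E = ms[2], s2G = (ms[1] - ms[2]) / r)
}
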