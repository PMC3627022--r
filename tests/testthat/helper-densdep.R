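# Shared fixtures for the densdep test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

# A ten-species stand configuration used by the survival-model experiments
# (community-level fits need several species; abundances keep every stage
# above the focal rule).
tenSpeciesConfig <- function() {
  standConfig(species = data.frame(
    species = sprintf("SP%02d", 1:10),
    growth_form = rep(c("CL", "CS", "UL", "US", "S"), 2),
    n_adults = c(120, 100, 110, 90, 70, 100, 80, 90, 70, 60),
    gamma = rep(c(1.5, 0.5, 1, 0, 2), 2),
    sigma = rep(c(3, 4, 2.5, 3.5, 2), 2),
    mu = rep(5, 10),
    beta = rep(c(0.3, 0, 0.2, 0, 0.5), 2),
    rho = rep(5, 10),
    pi0Sap = rep(0.8, 10),
    pi0Juv = rep(0.6, 10)))
}

# Independent brute-force oracle for the neighbourhood covariates: explicit
# per-seedling loops over quadrat mates and over every stem.
neighborCovariatesOracle <- function(seedlings, stems, radius = 10) {
  n <- nrow(seedlings)
  out <- data.frame(S_CON = integer(n), S_HET = integer(n),
                    B_CON = numeric(n), B_HET = numeric(n))
  for (i in seq_len(n)) {
    sCon <- 0L; sHet <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      if (seedlings$quadrat_id[j] == seedlings$quadrat_id[i]) {
        if (seedlings$species[j] == seedlings$species[i]) sCon <- sCon + 1L
        else sHet <- sHet + 1L
      }
    }
    bCon <- 0; bHet <- 0
    for (m in seq_len(nrow(stems))) {
      d <- sqrt((stems$x[m] - seedlings$x[i])^2 +
                (stems$y[m] - seedlings$y[i])^2)
      if (d > radius) next
      ba <- pi * (stems$dbh[m] / 200)^2
      if (stems$species[m] == seedlings$species[i]) bCon <- bCon + ba
      else bHet <- bHet + ba
    }
    out$S_CON[i] <- sCon; out$S_HET[i] <- sHet
    out$B_CON[i] <- bCon; out$B_HET[i] <- bHet
  }
  out
}

# Stem table with per-stage counts placed in the correct dbh intervals.
makeStems <- function(speciesCounts, window = Window(0, 100, 0, 100)) {
  rows <- do.call(rbind, lapply(seq_len(nrow(speciesCounts)), function(i) {
    p <- speciesCounts[i, ]
    dbh <- c(rep(1.2, p$sapling), rep(9.0, p$juvenile), rep(20, p$adult))
    n <- length(dbh)
    data.frame(species = p$species, dbh = dbh, growth_form = "CL",
               x = runif(n, window@xMin, window@xMax),
               y = runif(n, window@yMin, window@yMax))
  }))
  cbind(tag = sprintf("T%04d", seq_len(nrow(rows))), rows)
}
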