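#' @include AllClasses.R
NULL

# register-group residue frequency tables used by the generator.
# No biological claim beyond the qualitative structure of the heptad:
# the interface (a/d) is dominated by hydrophobic residues, e/g by
# charged residues, b/c/f by polar/hydrophilic ones.  Each table is a
# (major class, class mass, minor class) triple so that family-specific
# composition tilts can redistribute frequency within each class while
# preserving the class masses (e.g. the 0.8 hydrophobic mass at a/d).
registerFreqParts <- function() {
  list(
    AD = list(major = c(L = 30, I = 15, V = 12, M = 6, A = 10, F = 7),
              mass = 0.8,
              minor = c(K = 5, E = 5, Q = 4, N = 3, R = 4, S = 3,
                        T = 3, Y = 2, H = 1, D = 2, G = 2, C = 1,
                        W = 1, P = 1)),
    EG = list(major = c(E = 22, K = 18, R = 12, Q = 10, D = 8),
              mass = 0.7,
              minor = c(A = 6, L = 6, S = 5, N = 4, T = 4, I = 3,
                        G = 2, M = 2, H = 2, V = 2, Y = 1, F = 1,
                        C = 1, W = 1, P = 1)),
    BCF = list(major = c(S = 12, T = 10, N = 10, Q = 10, E = 10,
                         K = 10, D = 8, A = 8, G = 6, R = 5, H = 3),
               mass = 0.85,
               minor = c(L = 4, I = 2, V = 2, M = 1, F = 1, Y = 1,
                         C = 1, W = 1, P = 2)))
}

# assemble tables, optionally tilting the within-class weights by a
# multiplicative log-normal factor (one draw per residue); tiltSd = 0
# gives the untilted reference tables
registerFrequencies <- function(tiltSd = 0) {
  mk <- function(part) {
    major <- part$major
    minor <- part$minor
    if (tiltSd > 0) {
      major <- major * exp(stats::rnorm(length(major), 0, tiltSd))
      minor <- minor * exp(stats::rnorm(length(minor), 0, tiltSd))
    }
    w <- stats::setNames(rep(0, 20L), AA20)
    w[names(major)] <- major / sum(major) * part$mass
    w[names(minor)] <- minor / sum(minor) * (1 - part$mass)
    w
  }
  lapply(registerFreqParts(), mk)
}

# family-specific background (linker) composition: tilted BLOSUM62
# background
tiltedBackground <- function(bg, tiltSd) {
  if (tiltSd <= 0) return(bg)
  w <- bg * exp(stats::rnorm(length(bg), 0, tiltSd))
  w / sum(w)
}

#' Specification of a synthetic coiled-coil family simulation
#'
#' Default values define the package's reference simulation: 200
#' families of two-domain coiled-coil proteins (domains of 35-49
#' residues, five to seven heptads; linkers of 55-75 residues, giving
#' roughly 30% coiled-coil content), two descendant species at 0.55
#' per-site substitution divergence, and three architecture-matched
#' decoys per family in the second species.
#'
#' @param nFamilies number of homologous families.
#' @param ccFraction target coiled-coil fraction (documentation/QC
#'   value implied by the architecture; checked, not enforced).
#' @param nCCDomains coiled-coil domains per protein.
#' @param domainLength integer range (min, max) of domain lengths.
#' @param linkerLength integer range of linker lengths (there are
#'   \code{nCCDomains + 1} linkers).
#' @param divergence per-site substitution probability per descendant.
#' @param decoysPerFamily unrelated decoys (same architecture
#'   distribution and register composition) added to species 2.
#' @param compositionTilt standard deviation of the log-normal
#'   family-specific composition tilt. Every family (and every decoy)
#'   redistributes the within-class residue frequencies of its tables
#'   by this multiplicative noise, emulating the family- and
#'   genome-level composition biases of real proteomes; true homolog
#'   pairs share their family's tilt. 0 disables the tilt.
#' @param seed RNG seed.
#' @return a \code{list} of class \code{"familySpec"}.
#' @export
familySpec <- function(nFamilies = 200L, ccFraction = 0.30,
                       nCCDomains = 2L, domainLength = c(35L, 49L),
                       linkerLength = c(55L, 75L), divergence = 0.55,
                       decoysPerFamily = 3L, compositionTilt = 0,
                       seed = 42L) {
  spec <- list(nFamilies = as.integer(nFamilies),
               ccFraction = ccFraction,
               nCCDomains = as.integer(nCCDomains),
               domainLength = as.integer(domainLength),
               linkerLength = as.integer(linkerLength),
               divergence = divergence,
               decoysPerFamily = as.integer(decoysPerFamily),
               compositionTilt = compositionTilt,
               seed = as.integer(seed))
  if (spec$divergence < 0 || spec$divergence > 1)
    stop("divergence must be in [0, 1]")
  if (any(spec$domainLength < 7L) || any(spec$linkerLength < 7L))
    stop("all lengths must be at least 7 (one heptad)")
  if (spec$nFamilies < 1L || spec$nCCDomains < 1L)
    stop("need at least one family and one domain")
  if (diff(spec$domainLength) < 0L || diff(spec$linkerLength) < 0L)
    stop("length ranges must be (min, max)")
  class(spec) <- "familySpec"
  spec
}

withLocalSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic coiled-coil protein families
#'
#' Samples, per family, an ancestral protein whose coiled-coil domains
#' cycle the heptad registers (random phase per domain) with residues
#' drawn from register-group frequency tables (hydrophobic-enriched
#' interface, charge-enriched e/g, hydrophilic outside) and background
#' residues elsewhere. Two descendants are derived by independent
#' per-site substitution at the spec's divergence; substitutions inside
#' coiled-coils are drawn register-conditionally, so the heptad
#' structure is conserved while the sequence diverges. Decoys share the
#' coiled-coil architecture and register composition but are
#' ancestrally unrelated. Annotations report probability 0.95 inside
#' domains and 0.05 outside; registers are labelled inside domains.
#'
#' Fully reproducible: the same spec yields identical output.
#'
#' @param spec a [familySpec()].
#' @return list with \code{proteomes} (named list \code{sp1},
#'   \code{sp2} of [CCProtein-class] lists; decoys live in \code{sp2}),
#'   \code{gold} (\code{data.frame} \code{id1}, \code{id2} of true
#'   pairs) and \code{spec}.
#' @export
simulateFamilies <- function(spec = familySpec()) {
  stopifnot(inherits(spec, "familySpec"))
  bg <- blosum62Background()
  withLocalSeed(spec$seed, {
    sp1 <- list(); sp2 <- list()
    gold <- vector("list", spec$nFamilies)
    for (f in seq_len(spec$nFamilies)) {
      freqs <- registerFrequencies(spec$compositionTilt)
      bgF <- tiltedBackground(bg, spec$compositionTilt)
      arch <- sampleArchitecture(spec)
      anc <- sampleProtein(arch, freqs, bgF)
      d1 <- mutateProtein(anc, spec$divergence, freqs, bgF)
      d2 <- mutateProtein(anc, spec$divergence, freqs, bgF)
      id1 <- sprintf("fam%04d_sp1", f)
      id2 <- sprintf("fam%04d_sp2", f)
      sp1[[id1]] <- CCProtein(id1, paste(d1$res, collapse = ""),
                              anc$prob, anc$reg, species = "sp1")
      sp2[[id2]] <- CCProtein(id2, paste(d2$res, collapse = ""),
                              anc$prob, anc$reg, species = "sp2")
      gold[[f]] <- data.frame(id1 = id1, id2 = id2)
    }
    for (k in seq_len(spec$nFamilies * spec$decoysPerFamily)) {
      freqs <- registerFrequencies(spec$compositionTilt)
      bgF <- tiltedBackground(bg, spec$compositionTilt)
      arch <- sampleArchitecture(spec)
      dec <- sampleProtein(arch, freqs, bgF)
      id <- sprintf("dec%04d_sp2", k)
      sp2[[id]] <- CCProtein(id, paste(dec$res, collapse = ""),
                             dec$prob, dec$reg, species = "sp2")
    }
    list(proteomes = list(sp1 = sp1, sp2 = sp2),
         gold = do.call(rbind, gold), spec = spec)
  })
}

sampleArchitecture <- function(spec) {
  nd <- spec$nCCDomains
  dl <- sample(spec$domainLength[1]:spec$domainLength[2], nd,
               replace = TRUE)
  ll <- sample(spec$linkerLength[1]:spec$linkerLength[2], nd + 1L,
               replace = TRUE)
  phase <- sample(0:6, nd, replace = TRUE)
  list(domains = dl, linkers = ll, phase = phase)
}

# returns residues, registers ('-' outside domains), cc probabilities
sampleProtein <- function(arch, freqs, bg) {
  res <- character(0); reg <- character(0); prob <- numeric(0)
  nd <- length(arch$domains)
  for (k in seq_len(nd + 1L)) {
    nl <- arch$linkers[k]
    res <- c(res, sample(AA20, nl, replace = TRUE, prob = bg))
    reg <- c(reg, rep("-", nl))
    prob <- c(prob, rep(0.05, nl))
    if (k <= nd) {
      ndl <- arch$domains[k]
      r <- REGISTERS[((arch$phase[k] + seq_len(ndl) - 1L) %% 7L) + 1L]
      g <- unname(REGISTER_GROUPS[r])
      res <- c(res, vapply(g, function(gg)
        sample(AA20, 1L, prob = freqs[[gg]]), ""))
      reg <- c(reg, r)
      prob <- c(prob, rep(0.95, ndl))
    }
  }
  list(res = res, reg = reg, prob = prob)
}

mutateProtein <- function(anc, divergence, freqs, bg) {
  res <- anc$res
  hit <- stats::runif(length(res)) < divergence
  for (i in which(hit)) {
    if (anc$reg[i] == "-") {
      res[i] <- sample(AA20, 1L, prob = bg)
    } else {
      g <- unname(REGISTER_GROUPS[anc$reg[i]])
      res[i] <- sample(AA20, 1L, prob = freqs[[g]])
    }
  }
  list(res = res, reg = anc$reg, prob = anc$prob)
}
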