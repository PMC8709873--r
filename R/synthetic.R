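# Synthetic pedigrees, affection statuses and planted variants.
#
# The generator emulates the structure the analysis assumes: extended
# multi-generation families (default 7 generations, matching the 7-9
# generation depth of extended high-risk genealogies), a monogamous
# founder-spouse mating model in which every marry-in spouse is a new
# founder, affection assigned independently under stratified population
# rates with an optional per-family risk multiplier, and diploid genotype
# drops for a variant of frequency q under both the null (random founder
# alleles) and the alternative (single founder introduction) regime.
# Ground truth (lineage membership, introducer, transmission path) is
# recorded in the pedigree metadata sidecar so recovery experiments never
# re-derive it.

#' Default stratified rates: sex-stratified lifetime risk
#'
#' One birth-cohort band, stratified by sex, with cumulative lifetime risks
#' approximating US/Utah suicide mortality (about 2% for males, 0.5% for
#' females).
#'
#' @return a [PopulationRates] in cumulative mode.
#' @export
defaultRates <- function() {
  populationRates(c(male = 0.02, female = 0.005), mode = "cumulative")
}

#' Simulation configuration
#'
#' @param nGenerations pedigree depth (>= 2; default 7).
#' @param meanOffspring mean children per couple (Poisson; the apex couple's
#'   draw is zero-truncated so an ascertained family always has
#'   descendants). Default 2.
#' @param baseRates a [PopulationRates] (default [defaultRates()]).
#' @param riskMultiplier risk multiplier applied to lineage members
#'   (default 1 = null).
#' @param q allele frequency for null genotype drops (default 0.001).
#' @param plantedVariant `NULL`, or a list with fields `introducer` (a
#'   founder id, default the apex male founder), `penetrantTransmission`
#'   (force the allele down to all affected lineage descendants: the
#'   upper-bound alternative), and optional annotation fields `impact`,
#'   `sift`, `polyphen`, `consequence`.
#' @param deterministicOffspring use `round(meanOffspring)` children per
#'   couple instead of Poisson draws.
#' @param seed base seed; all stages derive keyed streams from it.
#' @param familyId family identifier.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(nGenerations = 7, meanOffspring = 2,
                      baseRates = defaultRates(), riskMultiplier = 1,
                      q = 0.001, plantedVariant = NULL,
                      deterministicOffspring = FALSE, seed = 1,
                      familyId = "FAM1") {
  stopifnot(nGenerations >= 2, meanOffspring >= 0, riskMultiplier > 0,
            is(baseRates, "PopulationRates"))
  .checkProb(q, "q")
  cfg <- list(nGenerations = as.integer(nGenerations),
              meanOffspring = meanOffspring, baseRates = baseRates,
              riskMultiplier = riskMultiplier, q = q,
              plantedVariant = plantedVariant,
              deterministicOffspring = isTRUE(deterministicOffspring),
              seed = seed, familyId = as.character(familyId))
  class(cfg) <- "SimConfig"
  cfg
}

.offspringDraw <- function(cfg, n, truncated = FALSE) {
  if (cfg$deterministicOffspring) return(rep(round(cfg$meanOffspring), n))
  k <- stats::rpois(n, cfg$meanOffspring)
  if (truncated) {
    while (any(k == 0)) k[k == 0] <- stats::rpois(sum(k == 0), cfg$meanOffspring)
  }
  k
}

#' Generate a branching-process pedigree
#'
#' Generation 1 is a single founder couple; every lineage member with
#' children marries a new marry-in founder of the opposite sex. Stratum is
#' the member's sex (one birth-cohort band). Truth (lineage membership,
#' generation, config) is stored in the metadata under `$truth`.
#'
#' @param cfg a [simConfig()].
#' @return a [Pedigree].
#' @export
generatePedigree <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$meanOffspring <= 0 ||
      (cfg$deterministicOffspring && round(cfg$meanOffspring) < 1)) {
    .famsegError("offspring mean yields no descendants: degenerate config",
                 "famseg_degenerate_error")
  }
  .setStream(cfg$seed, cfg$familyId, "pedigree")
  nextId <- 0L
  mk <- function(n) {
    ids <- sprintf("I%04d", nextId + seq_len(n))
    nextId <<- nextId + n
    ids
  }
  id_v <- fa_v <- mo_v <- sex_v <- character()
  gen_v <- integer()
  lin_v <- logical()
  addRows <- function(id, fa, mo, sex, gen, lineage) {
    id_v <<- c(id_v, id); fa_v <<- c(fa_v, fa); mo_v <<- c(mo_v, mo)
    sex_v <<- c(sex_v, sex)
    gen_v <<- c(gen_v, rep(gen, length(id)))
    lin_v <<- c(lin_v, rep(lineage, length(id)))
  }
  apex <- mk(2L)
  addRows(apex, c(NA, NA), c(NA, NA), c("male", "female"), 1L, TRUE)
  # couples carrying the next generation
  cFather <- apex[1]
  cMother <- apex[2]
  cKids <- .offspringDraw(cfg, 1L, truncated = TRUE)
  for (g in 2:cfg$nGenerations) {
    keep <- cKids > 0
    if (!any(keep)) break
    cFather <- cFather[keep]; cMother <- cMother[keep]; cKids <- cKids[keep]
    nk <- sum(cKids)
    kids <- mk(nk)
    kidFa <- rep(cFather, cKids)
    kidMo <- rep(cMother, cKids)
    sexes <- ifelse(stats::rbinom(nk, 1L, 0.5) == 1L, "male", "female")
    addRows(kids, kidFa, kidMo, sexes, g, TRUE)
    if (g == cfg$nGenerations) break
    nkNext <- .offspringDraw(cfg, nk)
    withSp <- which(nkNext > 0)
    if (length(withSp)) {
      sp <- mk(length(withSp))
      spSex <- ifelse(sexes[withSp] == "male", "female", "male")
      addRows(sp, rep(NA_character_, length(sp)), rep(NA_character_, length(sp)),
              spSex, g, FALSE)
      male <- sexes[withSp] == "male"
      cFather <- ifelse(male, kids[withSp], sp)
      cMother <- ifelse(male, sp, kids[withSp])
      cKids <- nkNext[withSp]
    } else {
      cKids <- integer()
    }
  }
  m <- data.frame(id = id_v, fatherId = fa_v, motherId = mo_v, sex = sex_v,
                  gen = gen_v, lineage = lin_v, stringsAsFactors = FALSE)
  m$affected <- "unknown"
  m$genotyped <- FALSE
  m$stratum <- m$sex
  truth <- list(config = cfg,
                lineage = m$id[m$lineage],
                marryIn = m$id[!m$lineage],
                generation = stats::setNames(m$gen, m$id))
  newPedigree(cfg$familyId,
              m[, c("id", "fatherId", "motherId", "sex", "affected",
                    "genotyped", "stratum")],
              metadata = list(truth = truth))
}

#' Expected pedigree size under the branching-process model
#'
#' Closed-form mean member count for [generatePedigree()]: with offspring
#' mean m over G generations, the expected lineage size per generation is
#' `E[L_2] = m / (1 - exp(-m))` (the apex couple's zero-truncated draw) and
#' `E[L_g] = E[L_2] m^(g-2)`; each member of generations 2..G-1 acquires a
#' marry-in spouse with probability `1 - exp(-m)`.
#'
#' @param cfg a [simConfig()].
#' @return the expected total member count.
#' @export
expectedPedigreeSize <- function(cfg) {
  G <- cfg$nGenerations
  m <- cfg$meanOffspring
  if (cfg$deterministicOffspring) {
    k <- round(m)
    L <- k^(seq_len(G - 1))
    return(2 + sum(L) + sum(L[seq_len(max(0, G - 2))]))
  }
  pSp <- 1 - exp(-m)
  L2 <- m / pSp
  L <- L2 * m^(0:(G - 2)) # generations 2..G
  2 + sum(L) + pSp * sum(L[seq_len(max(0, G - 2))])
}

#' Assign affection statuses under stratified rates
#'
#' Each member is affected independently with probability
#' `rate(stratum) * multiplier`, where the multiplier applies to lineage
#' members of a designated risk family (marry-in founders stay at the base
#' rate). Affected members are flagged genotyped (cases with DNA). The
#' truth sidecar records the per-member probability used.
#'
#' @param ped a [Pedigree] from [generatePedigree()].
#' @param cfg a [simConfig()]; `cfg$riskMultiplier` scales lineage risk.
#' @return the pedigree with statuses filled in.
#' @export
assignAffection <- function(ped, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  m <- ped@members
  rates <- cfg$baseRates
  if (rates@mode != "cumulative") {
    .famsegError("affection assignment needs cumulative-mode rates",
                 "famseg_config_error")
  }
  bad <- m$id[is.na(m$stratum) | !m$stratum %in% names(rates@rates)]
  if (length(bad)) {
    .famsegError(sprintf("unresolvable stratum for member(s): %s",
                         paste(bad, collapse = ", ")),
                 "famseg_config_error", ids = bad)
  }
  lineage <- ped@metadata$truth$lineage %||% m$id
  prob <- unname(rates@rates[m$stratum]) *
    ifelse(m$id %in% lineage, cfg$riskMultiplier, 1)
  if (any(prob > 1)) {
    .famsegError("risk multiplier pushes affection probability above 1",
                 "famseg_config_error")
  }
  .setStream(cfg$seed, cfg$familyId, "affection")
  m$affected <- ifelse(stats::runif(nrow(m)) < prob, "affected", "unaffected")
  m$genotyped <- m$affected == "affected"
  meta <- ped@metadata
  meta$truth$affectionProb <- stats::setNames(prob, m$id)
  meta$truth$riskMultiplier <- cfg$riskMultiplier
  newPedigree(ped@familyId, m, metadata = meta)
}

#' Plant (or null-drop) a single variant in a pedigree
#'
#' Null regime: every founder receives two i.i.d. Bernoulli(q) alleles and
#' alleles propagate by fair Mendelian transmission. Alternative regime
#' (`cfg$plantedVariant` set): one copy is introduced at the designated
#' founder; with `penetrantTransmission` the copy is additionally forced
#' down a shortest descent path to every affected lineage descendant (the
#' upper-bound alternative; such realizations are flagged non-Mendelian-null
#' in the truth sidecar, although the resulting genotype configuration is
#' still Mendelian-consistent since forcing only conditions transmission
#' outcomes).
#'
#' @param ped a [Pedigree].
#' @param cfg a [simConfig()].
#' @return list with `genotypes` (named 0/1/2 vector), `carrierIds`,
#'   `record` (a one-row annotated variant data.frame), and `truth`
#'   (introducer, forced path edges, meioses along the path, flags).
#' @export
plantVariant <- function(ped, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  m <- ped@members
  pv <- cfg$plantedVariant
  idx <- .dropIndex(ped)
  .setStream(cfg$seed, cfg$familyId, "variant")
  override <- list()
  truth <- list(penetrant = FALSE, introducer = NA_character_,
                pathEdges = matrix(character(), 0, 2), pathMeioses = NA_integer_)

  forced <- character(0)
  forcedEdges <- NULL
  if (!is.null(pv)) {
    introducer <- pv$introducer %||% ped@metadata$truth$lineage[1] %||%
      founders(ped)[1]
    if (!introducer %in% founders(ped)) {
      .domainError(sprintf("introducer '%s' is not a founder", introducer))
    }
    override[[introducer]] <- c(1L, NA)
    truth$introducer <- introducer
    if (isTRUE(pv$penetrantTransmission)) {
      truth$penetrant <- TRUE
      aff <- m$id[m$affected == "affected"]
      D <- .descentDistances(ped)
      vi <- match(introducer, idx$ids)
      targets <- aff[is.finite(D[vi, match(aff, idx$ids)])]
      lex <- order(idx$ids)
      edges <- list()
      for (t in targets) {
        cur <- match(t, idx$ids)
        while (cur != vi) {
          par <- c(idx$father[cur], idx$mother[cur])
          par <- par[!is.na(par) & is.finite(D[vi, par]) &
                       D[vi, par] == D[vi, cur] - 1]
          p <- par[which.min(match(par, lex))]
          edges[[paste0(p, ">", cur)]] <- c(p, cur)
          cur <- p
        }
      }
      forcedEdges <- do.call(rbind, edges)
      if (!is.null(forcedEdges)) {
        truth$pathEdges <- matrix(idx$ids[forcedEdges], ncol = 2,
                                  dimnames = list(NULL, c("parent", "child")))
      }
      truth$pathMeioses <- nrow(truth$pathEdges)
      forced <- targets
      truth$forcedCarriers <- unique(c(introducer, targets))
    }
  }

  al <- .dropAlleleChunk(idx, cfg$q, 1L, override)
  a1 <- vapply(al$a1, `[[`, numeric(1), 1L)
  a2 <- vapply(al$a2, `[[`, numeric(1), 1L)
  if (!is.null(forcedEdges)) {
    # push the introduced copy along each forced edge, in topological order
    for (i in idx$order) {
      hit <- forcedEdges[forcedEdges[, 2] == i, , drop = FALSE]
      if (!nrow(hit)) next
      p <- hit[1, 1]
      if (p == idx$father[i]) a1[i] <- max(a1[p], a2[p]) else a2[i] <- max(a1[p], a2[p])
    }
  }
  g <- stats::setNames(as.integer(a1 + a2), idx$ids)

  ann <- list(impact = "MODERATE", sift = "deleterious",
              polyphen = "probably_damaging", consequence = "missense")
  for (f in names(ann)) if (!is.null(pv[[f]])) ann[[f]] <- pv[[f]]
  carrierIds <- names(g)[g > 0]
  rec <- data.frame(
    id = sprintf("%s_var", cfg$familyId), chrom = "2", pos = 50847195L,
    ref = "G", alt = "A", rsid = NA_character_,
    impact = ann$impact, sift = ann$sift, polyphen = ann$polyphen,
    consequence = ann$consequence,
    caseHet = sum(g == 1L & m$affected == "affected"),
    caseHom = sum(g == 2L & m$affected == "affected"),
    caseN = sum(m$affected == "affected"),
    famCarriers = sum(g[m$id[m$genotyped]] > 0),
    stringsAsFactors = FALSE)
  list(genotypes = g, carrierIds = carrierIds, record = rec, truth = truth)
}

#' Generate, screen and summarize a cohort of synthetic families
#'
#' Drives the aggregation calibration and planted-signal recovery
#' experiments: families are generated and screened one at a time (so
#' arbitrarily large cohorts fit in memory), the first
#' `round(plantedFraction * nFamilies)` families receiving
#' `plantedMultiplier` times the base lineage risk.
#'
#' @param nFamilies number of families.
#' @param cfg a [simConfig()] template (family id and seed are re-keyed per
#'   family).
#' @param alpha familial significance threshold.
#' @param plantedFraction fraction of families with elevated risk.
#' @param plantedMultiplier risk multiplier for planted families.
#' @param seed base seed.
#' @return data.frame with one row per family: `familyId`, `planted`,
#'   `observed`, `expected`, `sir`, `pValue`, `highRisk`.
#' @export
riskCohortExperiment <- function(nFamilies, cfg = simConfig(), alpha = 0.01,
                                 plantedFraction = 0, plantedMultiplier = 1,
                                 seed = 1) {
  stopifnot(nFamilies >= 1)
  nPlanted <- round(plantedFraction * nFamilies)
  rows <- vector("list", nFamilies)
  for (i in seq_len(nFamilies)) {
    fid <- sprintf("F%05d", i)
    planted <- i <= nPlanted
    cfgi <- cfg
    cfgi$familyId <- fid
    cfgi$seed <- seed
    cfgi$riskMultiplier <- if (planted) plantedMultiplier else 1
    ped <- assignAffection(generatePedigree(cfgi), cfgi)
    st <- sirTest(sum(ped@members$affected == "affected"),
                  expectedCount(ped, cfgi$baseRates))
    rows[[i]] <- data.frame(
      familyId = fid, planted = planted, observed = st$observed,
      expected = st$expected, sir = st$sir, pValue = st$pValue,
      highRisk = st$pValue < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}
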