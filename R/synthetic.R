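#' Construct a SyntheticConfig
#'
#' Helper constructor for [SyntheticConfig-class]; any slot can be
#' overridden by name, the rest keep the study-condition defaults.
#'
#' @param ... named slot overrides (e.g. `nPathogenic = 10L`, `seed = 7L`).
#' @return a validated [SyntheticConfig-class].
#' @export
#' @examples
#' syntheticConfig(seed = 42L)
syntheticConfig <- function(...) {
  args <- list(...)
  intSlots <- c("nPathogenic", "nBenign", "nStructures", "proteinLength",
                "seed")
  for (s in intersect(names(args), intSlots))
    args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SyntheticConfig"), args))
}

#' Generate a synthetic variant cohort with per-structure ddG observations
#'
#' Draws a two-group cohort with the statistical structure the pipeline is
#' designed for: each variant has a latent true ddG ~ Normal(group mean,
#' group SD); every structure chain resolving the variant contributes an
#' observation latent + Normal(0, per-structure noise SD). A configurable
#' fraction of variants (default 95%) is resolved in all chains, the rest
#' in a single chain. RSA is drawn from a buried-skewed mixture for
#' pathogenic variants (Beta(2,8) with the configured burial probability,
#' else uniform) and near-uniformly for benign ones. REVEL-like scores are
#' a logistic transform of the standardised latent ddG plus
#' Normal(0, 0.15) noise, clipped to `[0,1]` — a fixture model, not a
#' claim about the real predictor. Deterministic given `cfg@seed`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return list with elements `variants` (variant-table layout, see
#'   [readVariantTsv()]), `ddg` (ddG record layout, see [parseDdgTsv()]),
#'   and `truth` (per-variant generator state: `id, position, ref_aa,
#'   alt_aa, group, latent_ddg, rsa, n_structures`).
#' @export
generateCohort <- function(cfg = syntheticConfig()) {
  stopifnot(is(cfg, "SyntheticConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nPathogenic + cfg@nBenign
  if (n == 0L)
    stop("cohort is empty: nPathogenic + nBenign must be >= 1")
  group <- c(rep("pathogenic", cfg@nPathogenic),
             rep("benign", cfg@nBenign))
  # distinct positions while they last; recycled with different alt residues
  # when the cohort outgrows the protein
  if (n <= cfg@proteinLength) {
    position <- sample.int(cfg@proteinLength, n)
  } else {
    position <- c(sample.int(cfg@proteinLength),
                  sample.int(cfg@proteinLength, n - cfg@proteinLength,
                             replace = TRUE))
  }
  refByPos <- structure(sample(AA1, cfg@proteinLength, replace = TRUE),
                        names = as.character(seq_len(cfg@proteinLength)))
  ref <- unname(refByPos[as.character(position)])
  alt <- unname(vapply(ref, function(r) sample(setdiff(AA1, r), 1L),
                       character(1)))
  isPath <- group == "pathogenic"
  latent <- numeric(n)
  latent[isPath] <- rnorm(sum(isPath), cfg@ddgMeanPath, cfg@ddgSdPath)
  latent[!isPath] <- rnorm(sum(!isPath), cfg@ddgMeanBenign, cfg@ddgSdBenign)
  # burial profile
  rsa <- numeric(n)
  buriedDraw <- runif(n) < cfg@buriedFractionPath
  nb <- sum(isPath & buriedDraw)
  rsa[isPath & buriedDraw] <- rbeta(nb, 2, 8)
  rsa[isPath & !buriedDraw] <- runif(sum(isPath & !buriedDraw))
  rsa[!isPath] <- runif(sum(!isPath))
  # REVEL fixture: logistic in the latent ddG, standardised against the
  # configured grand mean and average group SD
  mu0 <- (cfg@ddgMeanPath + cfg@ddgMeanBenign) / 2
  sd0 <- (cfg@ddgSdPath + cfg@ddgSdBenign) / 2
  revel <- plogis((latent - mu0) / sd0) + rnorm(n, 0, cfg@revelNoiseSd)
  revel <- pmin(1, pmax(0, revel))
  af <- ifelse(isPath, NA_real_,
               pmin(1, rlnorm(n, meanlog = log(1e-5), sdlog = 1.5)))
  nFull <- round(cfg@fullCoverageFraction * n)
  nCov <- integer(n)
  fullIdx <- if (nFull > 0L) sample.int(n, nFull) else integer(0)
  nCov[fullIdx] <- cfg@nStructures
  nCov[nCov == 0L] <- 1L
  id <- sprintf("var%04d", seq_len(n))
  variants <- data.frame(
    id = id, position = position, ref_aa = ref, alt_aa = alt,
    in_hgmd_dm = isPath, in_gnomad = !isPath, in_sgcd = FALSE,
    allele_frequency = af, revel = revel,
    cdna_notation = NA_character_, stringsAsFactors = FALSE)
  structIds <- sprintf("TOY%02d", seq_len(cfg@nStructures))
  sel <- lapply(seq_len(n), function(i)
    if (nCov[i] == cfg@nStructures) seq_len(cfg@nStructures)
    else sample.int(cfg@nStructures, nCov[i]))
  nObs <- sum(nCov)
  ddg <- data.frame(
    structure_id = structIds[unlist(sel)], chain_id = "A",
    position = rep(position, nCov), ref_aa = rep(ref, nCov),
    alt_aa = rep(alt, nCov),
    ddg = rep(latent, nCov) + rnorm(nObs, 0, cfg@perStructureNoiseSd),
    stringsAsFactors = FALSE)
  truth <- data.frame(id = id, position = position, ref_aa = ref,
                      alt_aa = alt, group = group, latent_ddg = latent,
                      rsa = rsa, n_structures = nCov,
                      stringsAsFactors = FALSE)
  list(variants = variants, ddg = ddg, truth = truth)
}

#' Generate a toy helical structure as PDB text
#'
#' Builds an ideal alpha-helical C-alpha trace (rise 1.5 A per residue,
#' 100 degrees per residue, helix radius 2.3 A) with one pseudo side-chain
#' sphere (CB) per residue placed radially outward. With two chain ids the
#' second helix is placed parallel to and in contact with the first so
#' that interface residues are occluded by construction (for dRSA / dddG
#' fixtures). The output is valid fixed-width PDB text.
#'
#' @param nResidues residues per chain (>= 3).
#' @param chainIds one or two chain identifiers (default `"A"`).
#' @param seed RNG seed for the residue-type sequence.
#' @param contactDistance axis-to-axis distance of the second chain
#'   (default 7 A; small enough that side chains of facing residues
#'   occlude each other).
#' @return character vector of PDB lines.
#' @export
#' @examples
#' pdb <- generateToyStructure(10)
#' s <- readPdb(pdb, structureId = "toy")
generateToyStructure <- function(nResidues, chainIds = "A", seed = 1L,
                                 contactDistance = 7.0) {
  stopifnot(nResidues >= 3L, length(chainIds) %in% c(1L, 2L))
  set.seed(as.integer(seed))
  rise <- 1.5; twist <- 100 * pi / 180; helixR <- 2.3; cbOut <- 1.6
  serial <- 0L
  lines <- character(0)
  for (ci in seq_along(chainIds)) {
    # chain B sits alongside chain A, rotated so side chains face inward
    xoff <- if (ci == 1L) 0 else contactDistance
    aa <- sample(AA1, nResidues, replace = TRUE)
    for (i in seq_len(nResidues)) {
      ang <- twist * (i - 1)
      ca <- c(helixR * cos(ang) + xoff, helixR * sin(ang), rise * (i - 1))
      # CB points away from the helix axis; for chain B, toward chain A
      dir <- c(cos(ang), sin(ang), 0)
      if (ci == 2L) dir <- c(-abs(cos(ang)), sin(ang), 0)
      cb <- ca + cbOut * dir
      res3 <- AA3[aa[i]]
      for (at in list(list(n = "CA", p = ca), list(n = "CB", p = cb))) {
        if (aa[i] == "G" && at$n == "CB") next
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, at$n, res3, chainIds[ci], i,
          at$p[1], at$p[2], at$p[3], 1.0, 0.0))
      }
    }
    lines <- c(lines, "TER")
  }
  c(lines, "END")
}
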