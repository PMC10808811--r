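#' Parameters of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pipeline is built
#' to analyze: species-specific healthy baseline gut microHIs, a
#' dysbiotic subpopulation with a depressed microHI and spiked
#' health-negative taxa, water samples whose environmental microHI varies
#' by site and year, and water-to-gut compositional coupling present only
#' in designated ecotypes. Defaults are anchored to the field situation
#' the pipeline targets: per-species baselines averaging 0.71, a
#' dysbiosis prevalence of 30% with a mean microHI depression of 0.13
#' (0.71 healthy vs 0.58 unhealthy), environmental microHIs spanning
#' 0.6-0.9 across site-year units, and a coupling coefficient of 0.5 for
#' carnivorous species and 0 elsewhere.
#'
#' @param species character vector of species names (default 8 species,
#'   two per ecotype)
#' @param ecotypes ecotype of each species
#' @param n_gut gut samples per species (recycled)
#' @param n_sites,n_years site-year grid
#' @param n_water_per_unit water samples per site-year unit (recycled
#'   over units)
#' @param n_taxa,n_linked,n_key total taxa, phenotype-linked taxa among
#'   them, and spiked key taxa among those
#' @param baselines per-species healthy mean gut microHI targets
#' @param prevalence probability that a gut sample is dysbiotic
#' @param gap mean microHI depression of dysbiotic samples
#' @param env_microhi per-unit water environmental microHI targets
#' @param beta named water-to-gut compositional mixing rate per ecotype;
#'   the expected slope of gut on environmental microHI for that ecotype
#' @param concentration Dirichlet concentration of per-sample gut
#'   compositional noise (larger = less noise)
#' @param water_concentration Dirichlet concentration of water samples;
#'   much higher than the gut value because replicate filters from a
#'   well-mixed river transect vary far less than gut communities do
#'   between individuals
#' @param personal_weight weight of the idiosyncratic (random-support,
#'   microHI-neutral) displacement given to dysbiotic samples, which
#'   pushes them out of their conspecific dendrogram branches
#' @param spike_key_share share of the dysbiotic spike mass placed on
#'   the key taxa at the average key water abundance; the realized share
#'   scales with the local water abundance of the keys (the rest of the
#'   spike goes to high-load phenotype-linked taxa)
#' @param keys_water_share mean absolute share of the water composition
#'   held by the key taxa; the realized share tiles 1.5x/0.5x of this
#'   value over site-year units in an ABBA pattern, so key abundance in
#'   water varies independently of the environmental health gradient
#' @param carryover passive intake coefficient: every gut sample picks
#'   up the local water key taxa at `carryover` times their water
#'   abundance, the compositional channel through which environmental
#'   health-negative taxa reach all guts
#' @param core_clean,core_dirty numbers of phenotype-free and
#'   phenotype-linked taxa in each species' core composition
#' @param water_clean,water_dirty same for the shared water support
#' @param k_healthy,k_gap_frac,k_sd Fulton's K of healthy fish, the
#'   relative K deficit of dysbiotic fish (kept under 9%), and the K
#'   noise
#' @param years calendar years of the sampling campaigns (length
#'   `n_years`)
#' @param level taxonomic level tag of the emitted tables
#' @param seed integer seed
#' @return a validated `simulation_params` list
#' @export
simulation_params <- function(species = sprintf("Sp%02d", 1:8),
                              ecotypes = rep(MICROHI_ECOTYPES, each = 2),
                              n_gut = 25,
                              n_sites = 3, n_years = 2,
                              n_water_per_unit = 5,
                              n_taxa = 150, n_linked = 100, n_key = 3,
                              baselines = NULL,
                              prevalence = 0.30, gap = 0.13,
                              env_microhi = NULL,
                              beta = c("filter-feeding" = 0,
                                       "scraper-feeding" = 0,
                                       "omnivorous" = 0,
                                       "carnivorous" = 0.5),
                              concentration = 50,
                              water_concentration = 2000,
                              personal_weight = 0.62,
                              spike_key_share = 0.25,
                              keys_water_share = 0.06,
                              carryover = 0.3,
                              core_clean = 15, core_dirty = 10,
                              water_clean = 20, water_dirty = 25,
                              k_healthy = 1.02, k_gap_frac = 0.06,
                              k_sd = 0.04,
                              years = NULL, level = "genus",
                              seed = NULL) {
  n_sp <- length(species)
  stopifnot(n_sp >= 1, length(ecotypes) == n_sp)
  if (any(!ecotypes %in% MICROHI_ECOTYPES))
    stop_validation("unknown ecotype in simulation params")
  n_gut <- rep_len(as.integer(n_gut), n_sp)
  n_units <- n_sites * n_years
  n_water_per_unit <- rep_len(as.integer(n_water_per_unit), n_units)
  if (is.null(baselines))
    baselines <- 0.71 + seq(-0.07, 0.07, length.out = n_sp)
  if (is.null(env_microhi))
    env_microhi <- if (n_units == 1) 0.71
                   else seq(0.60, 0.90, length.out = n_units)
  if (is.null(years)) years <- seq(2023 - n_years, 2022)
  stopifnot(length(baselines) == n_sp, length(env_microhi) == n_units,
            length(years) == n_years,
            n_taxa >= n_linked, n_linked >= n_key, n_key >= 1,
            prevalence >= 0, prevalence <= 1, gap >= 0,
            all(baselines > 0 & baselines < 1),
            all(env_microhi > 0 & env_microhi < 1),
            all(beta >= 0 & beta <= 0.9),
            all(MICROHI_ECOTYPES %in% names(beta)),
            concentration > 0, water_concentration > 0,
            personal_weight >= 0,
            personal_weight + 0.05 < 1,
            spike_key_share > 0, spike_key_share <= 1,
            keys_water_share > 0, keys_water_share < 0.5,
            carryover >= 0, carryover <= 1,
            core_clean + core_dirty <= n_taxa,
            water_clean + water_dirty <= n_taxa,
            core_clean >= 1, core_dirty >= 1,
            water_clean >= 1, water_dirty >= n_key,
            k_healthy > 0, k_gap_frac >= 0, k_gap_frac < 0.09)
  p <- list(species = species, ecotypes = ecotypes, n_gut = n_gut,
            n_sites = as.integer(n_sites), n_years = as.integer(n_years),
            n_water_per_unit = n_water_per_unit,
            n_taxa = as.integer(n_taxa), n_linked = as.integer(n_linked),
            n_key = as.integer(n_key),
            baselines = as.numeric(baselines),
            prevalence = prevalence, gap = gap,
            env_microhi = as.numeric(env_microhi), beta = beta,
            concentration = concentration,
            water_concentration = water_concentration,
            personal_weight = personal_weight,
            spike_key_share = spike_key_share,
            keys_water_share = keys_water_share,
            carryover = carryover,
            core_clean = as.integer(core_clean),
            core_dirty = as.integer(core_dirty),
            water_clean = as.integer(water_clean),
            water_dirty = as.integer(water_dirty),
            k_healthy = k_healthy, k_gap_frac = k_gap_frac, k_sd = k_sd,
            years = as.integer(years), level = level,
            seed = if (is.null(seed)) NULL else as.integer(seed))
  class(p) <- "simulation_params"
  p
}

#' Cohort shapes echoing the middle-Yangtze field campaigns
#'
#' `"middle-yangtze-2022"` reproduces the shape of a single-section,
#' single-year survey: 14 species across the four ecotypes with
#' per-species sample counts between 2 and 41 (214 gut samples in all)
#' and 30 water samples. `"two-year"` adds a second sampling year with a
#' higher environmental microHI (0.83 vs 0.71) and 13 water samples.
#'
#' @param name preset name
#' @param ... overrides passed on to [simulation_params()]
#' @return a `simulation_params` list
#' @export
study_preset <- function(name = c("middle-yangtze-2022", "two-year"), ...) {
  name <- match.arg(name)
  sp <- c("L.crassilabris", "L.longirostris", "P.vachelli", "P.nitidus",
          "P.fulvidraco", "P.tenuis", "S.meridionalis", "H.molitrix",
          "A.nobilis", "C.heterodon", "X.argentea", "S.chuatsi",
          "S.kneri", "C.brachygnathus")
  eco <- c(rep("carnivorous", 7), "filter-feeding", "filter-feeding",
           "omnivorous", "scraper-feeding", "carnivorous", "carnivorous",
           "carnivorous")
  counts <- c(31, 41, 4, 11, 16, 6, 2, 4, 5, 35, 14, 9, 5, 31)
  base <- list(species = sp, ecotypes = eco, n_gut = counts,
               baselines = 0.71 + seq(-0.07, 0.07, length.out = length(sp)))
  preset <- switch(name,
    "middle-yangtze-2022" = c(base, list(
      n_sites = 1, n_years = 1, n_water_per_unit = 30,
      env_microhi = 0.71, years = 2022)),
    "two-year" = c(base, list(
      n_sites = 1, n_years = 2, n_water_per_unit = c(13, 30),
      env_microhi = c(0.83, 0.71), years = c(2020, 2022))))
  do.call(simulation_params, utils::modifyList(preset, list(...)))
}

# two-pool composition solver: mixes a clean (zero-load) and a dirty
# (phenotype-carrying) raw composition so the phenotype-weighted microHI
# of the result equals `target` exactly
mix_to_target <- function(clean_comp, dirty_comp, load, target) {
  l_dirty <- sum(dirty_comp * load)
  a <- (1 - target) / l_dirty
  if (!is.finite(a) || a <= 0 || a > 1)
    stop_validation(paste("infeasible target microHI %.3f: the dirty pool",
                          "carries mean load %.3f, so reachable targets lie",
                          "in [%.3f, 1)"), target, l_dirty, 1 - l_dirty)
  (1 - a) * clean_comp + a * dirty_comp
}

# sparse composition on a random support whose phenotype-weighted microHI
# equals `target`: the idiosyncratic displacement given to dysbiotic
# samples. Random support makes each displacement point in its own
# direction, so dysbiotic samples scatter instead of forming branches of
# their own; solving to `target` keeps the displacement microHI-neutral.
random_sparse_comp <- function(taxa, clean, dirty, load, target,
                               k = 4, max_tries = 20) {
  for (try in seq_len(max_tries)) {
    cc <- stats::setNames(numeric(length(taxa)), taxa)
    cc[sample(clean, min(k, length(clean)))] <-
      rdirichlet1(rep(0.8, min(k, length(clean))))
    dd <- stats::setNames(numeric(length(taxa)), taxa)
    dsel <- sample(dirty, min(k, length(dirty)))
    dd[dsel] <- rdirichlet1(rep(0.8, length(dsel)))
    l_dirty <- sum(dd * load)
    a <- (1 - target) / l_dirty
    if (is.finite(a) && a > 0 && a <= 1) return((1 - a) * cc + a * dd)
  }
  # fall back to the dirty pool alone; realized microHI 1 - l_dirty is
  # the closest reachable value
  dd
}

#' Generate a paired gut/water cohort with known ground truth
#'
#' Builds, per site-year unit, a water base composition whose
#' phenotype-weighted microHI hits the unit's target exactly, and per
#' species a core composition whose microHI is solved so that after
#' water mixing (at the species' ecotype coupling rate `beta`) the
#' expected healthy gut microHI equals the configured baseline. Gut
#' samples are Dirichlet draws around the core/water mixture; dysbiotic
#' samples (Bernoulli with the configured prevalence) additionally
#' receive a spike on the key taxa - scaled with the local water
#' abundance of those taxa, so they genuinely track the environment -
#' plus an idiosyncratic low-concentration displacement that pushes them
#' out of their conspecific dendrogram branches. Body length and weight
#' are drawn so that healthy fish have a slightly higher Fulton's K than
#' dysbiotic fish.
#'
#' @param params a [simulation_params()] list
#' @param seed integer seed (defaults to `params$seed`)
#' @return a `microhi_simulation` list: `gut` and `water`
#'   [abundance_table()]s, `map` (phenotype map over all taxa), `meta`
#'   (sample metadata), `community` (community structure), `taxonomy`
#'   (taxon/genus/family map), and `truth` (per-sample true status,
#'   per-species baselines and solved core microHIs, per-ecotype beta,
#'   key taxon identities, per-unit environmental microHI)
#' @export
simulate_dataset <- function(params = simulation_params(),
                             seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  with_local_seed(seed, {
    taxa <- sprintf("T%03d", seq_len(p$n_taxa))
    keys <- taxa[seq_len(p$n_key)]
    dirty <- taxa[seq_len(p$n_linked)]
    clean <- setdiff(taxa, dirty)

    # phenotype weights: keys carry all three phenotypes strongly; the
    # other linked taxa draw each phenotype independently
    w <- matrix(0, nrow = p$n_taxa, ncol = 3,
                dimnames = list(taxa, c("pathogenic", "mobile", "stress")))
    w[keys, ] <- rep(c(1, 0.8, 0.8), each = p$n_key)
    others <- setdiff(dirty, keys)
    for (ph in colnames(w))
      w[others, ph] <- stats::rbinom(length(others), 1, 0.8) *
        stats::runif(length(others), 0.5, 1)
    none <- others[rowSums(w[others, , drop = FALSE]) == 0]
    if (length(none)) w[none, "pathogenic"] <- stats::runif(length(none), 0.5, 1)
    load <- rowMeans(w)
    map <- phenotype_map(data.frame(taxon = taxa,
                                    pathogenic = w[, "pathogenic"],
                                    mobile = w[, "mobile"],
                                    stress = w[, "stress"],
                                    stringsAsFactors = FALSE))

    # taxonomy for level aggregation: key taxa keep their own genus and
    # family so aggregation never dilutes them
    gen <- fam <- character(p$n_taxa)
    gen[seq_len(p$n_key)] <- sprintf("KG%02d", seq_len(p$n_key))
    fam[seq_len(p$n_key)] <- sprintf("KF%02d", seq_len(p$n_key))
    rest <- seq(p$n_key + 1, p$n_taxa)
    gen[rest] <- sprintf("G%03d", ceiling(seq_along(rest) / 2))
    fam[rest] <- sprintf("F%03d", ceiling(seq_along(rest) / 5))
    taxonomy <- data.frame(taxon = taxa, genus = gen, family = fam,
                           stringsAsFactors = FALSE)

    # site-year units
    sites <- sprintf("S%02d", seq_len(p$n_sites))
    grid <- expand.grid(site = sites, year = p$years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$year, grid$site), , drop = FALSE]
    n_units <- nrow(grid)
    unit_names <- paste(grid$site, grid$year, sep = ":")

    # shared water support. The dirty mass fraction is solved per unit
    # to hit the unit's environmental microHI exactly; the share of the
    # dirty pool held by the key taxa varies site to site (alternating
    # high/low), deliberately out of phase with the health gradient, so
    # key-taxon water abundance carries its own spatial signal rather
    # than being a mirror image of the environmental microHI
    water_dirty_taxa <- c(keys, sample(others, p$water_dirty - p$n_key))
    water_clean_taxa <- sample(clean, p$water_clean)
    u_c <- stats::setNames(numeric(p$n_taxa), taxa)
    u_c[water_clean_taxa] <- rdirichlet1(rep(2, p$water_clean))
    key_split <- rdirichlet1(rep(8, p$n_key))
    other_dirty_comp <- stats::setNames(numeric(p$n_taxa), taxa)
    other_dirty_comp[setdiff(water_dirty_taxa, keys)] <-
      rdirichlet1(rep(2, p$water_dirty - p$n_key))
    # the keys' absolute water share follows an ABBA-tiled high/low
    # pattern, orthogonal to monotone environmental gradients by
    # construction; the rest of the composition is solved so the whole
    # sample still hits the unit's microHI target exactly
    key_share_u <- p$keys_water_share *
      rep_len(c(1.5, 0.5, 0.5, 1.5), n_units)
    l_keys <- sum(key_split * load[keys])
    water_base <- matrix(0, nrow = p$n_taxa, ncol = n_units,
                         dimnames = list(taxa, unit_names))
    for (k in seq_len(n_units)) {
      s <- key_share_u[k]
      rest_load <- (1 - p$env_microhi[k]) - s * l_keys
      if (rest_load <= 0)
        stop_validation(paste("infeasible environmental microHI %.2f:",
                              "the key taxa alone carry load %.3f"),
                        p$env_microhi[k], s * l_keys)
      rest_target <- 1 - rest_load / (1 - s)
      wb <- (1 - s) * mix_to_target(u_c, other_dirty_comp, load, rest_target)
      wb[keys] <- s * key_split
      water_base[, k] <- wb
    }
    key_water <- colSums(water_base[keys, , drop = FALSE])
    key_water_mean <- mean(key_water)

    # species cores, solved so that after water mixing and passive
    # key-taxon carryover the expected healthy gut microHI equals the
    # configured baseline (gut samples are spread evenly over units)
    n_sp <- length(p$species)
    cores <- matrix(0, nrow = p$n_taxa, ncol = n_sp,
                    dimnames = list(taxa, p$species))
    h_keys <- 1 - sum(key_split * load[keys])
    carry_tot <- p$carryover * key_water          # per-unit carryover mass
    h_core <- numeric(n_sp)
    for (j in seq_len(n_sp)) {
      b <- p$beta[[p$ecotypes[j]]]
      # E[microHI | unit u] = ((1-b) h_core + b h_env_u + carry_u h_keys)
      #                      / (1 + carry_u); solve mean over units = baseline
      M <- mean((b * p$env_microhi + carry_tot * h_keys) / (1 + carry_tot))
      W <- mean((1 - b) / (1 + carry_tot))
      h_core[j] <- (p$baselines[j] - M) / W
      if (h_core[j] <= 0 || h_core[j] >= 1)
        stop_validation("infeasible baseline %.2f for species %s under beta %.2f",
                        p$baselines[j], p$species[j], b)
      v_c <- stats::setNames(numeric(p$n_taxa), taxa)
      v_c[sample(clean, p$core_clean)] <- rdirichlet1(rep(2, p$core_clean))
      v_d <- stats::setNames(numeric(p$n_taxa), taxa)
      v_d[sample(others, p$core_dirty)] <- rdirichlet1(rep(2, p$core_dirty))
      cores[, j] <- mix_to_target(v_c, v_d, load, h_core[j])
    }

    # gut samples
    n_gut_total <- sum(p$n_gut)
    gut <- matrix(0, nrow = p$n_taxa, ncol = n_gut_total,
                  dimnames = list(taxa, sprintf("G%04d", seq_len(n_gut_total))))
    g_species <- character(n_gut_total)
    g_unit <- integer(n_gut_total)
    g_status <- character(n_gut_total)
    idx <- 0L
    for (j in seq_len(n_sp)) {
      b <- p$beta[[p$ecotypes[j]]]
      units_j <- rep_len(seq_len(n_units) + (j - 1L), p$n_gut[j]) %%
        n_units + 1L
      for (i in seq_len(p$n_gut[j])) {
        idx <- idx + 1L
        u <- units_j[i]
        g_species[idx] <- p$species[j]
        g_unit[idx] <- u
        x <- rdirichlet1(p$concentration * cores[, j])
        mix_base <- cores[, j]
        if (b > 0) {
          xw <- rdirichlet1(p$concentration * water_base[, u])
          x <- (1 - b) * x + b * xw
          mix_base <- (1 - b) * cores[, j] + b * water_base[, u]
        }
        # passive carryover: every gut picks up the local water key taxa
        # in proportion to their water concentration
        if (p$carryover > 0) {
          pass <- stats::setNames(numeric(p$n_taxa), taxa)
          pass[keys] <- p$carryover * water_base[keys, u]
          x <- (x + pass) / (1 + sum(pass))
          mix_base <- (mix_base + pass) / (1 + sum(pass))
        }
        dys <- stats::runif(1) < p$prevalence
        g_status[idx] <- if (dys) "unhealthy" else "healthy"
        if (dys) {
          # the key share of the spike scales with the local water
          # abundance of the key taxa and mirrors their water profile,
          # so gut enrichment tracks water taxon by taxon; the rest of
          # the spike goes to high-load bystander taxa, keeping the
          # microHI depression solvable at a near-constant mixing weight
          q_u <- min(1, p$spike_key_share * key_water[u] / key_water_mean)
          spike <- stats::setNames(numeric(p$n_taxa), taxa)
          spike[keys] <- q_u * water_base[keys, u] / key_water[u]
          # bystander pool excludes water-borne taxa: the opportunists
          # blooming in a disordered gut are resident taxa, so their
          # abundance carries no water signal
          resident <- setdiff(others, water_dirty_taxa)
          high_load <- resident[load[resident] >=
                                  stats::quantile(load[resident], 0.7)]
          extra <- sample(high_load, min(5, length(high_load)))
          spike[extra] <- spike[extra] + (1 - q_u) *
            rdirichlet1(rep(1, length(extra)))
          h_spike <- 1 - sum(spike * load)
          h_mix <- sum(mix_base * (1 - load))
          delta <- p$gap / max(h_mix - h_spike, 0.05)
          delta <- min(delta, 0.9 - p$personal_weight)
          # displacement support avoids the species' own core taxa: the
          # disordered community is rebuilt from foreign taxa, not a
          # reshuffle of the resident ones
          core_taxa <- taxa[cores[, j] > 0]
          personal <- random_sparse_comp(taxa, setdiff(clean, core_taxa),
                                         setdiff(others, core_taxa), load,
                                         target = h_mix)
          x <- (1 - delta - p$personal_weight) * x + delta * spike +
            p$personal_weight * personal
        }
        gut[, idx] <- x
      }
    }

    # water samples
    n_water_total <- sum(p$n_water_per_unit)
    water <- matrix(0, nrow = p$n_taxa, ncol = n_water_total,
                    dimnames = list(taxa,
                                    sprintf("W%04d", seq_len(n_water_total))))
    w_unit <- integer(n_water_total)
    idx <- 0L
    for (u in seq_len(n_units)) {
      for (i in seq_len(p$n_water_per_unit[u])) {
        idx <- idx + 1L
        w_unit[idx] <- u
        water[, idx] <- rdirichlet1(p$water_concentration * water_base[, u])
      }
    }

    # morphometrics: healthy K slightly above dysbiotic K
    sp_len <- stats::setNames(stats::rlnorm(n_sp, log(22), 0.25), p$species)
    len <- stats::rlnorm(n_gut_total, log(sp_len[g_species]), 0.08)
    k_target <- ifelse(g_status == "healthy", p$k_healthy,
                       p$k_healthy * (1 - p$k_gap_frac))
    k_draw <- pmax(stats::rnorm(n_gut_total, k_target, p$k_sd), 0.5)
    weight <- k_draw * len^3 / 100

    meta <- sample_metadata(data.frame(
      sample_id = c(colnames(gut), colnames(water)),
      source = c(rep("gut", n_gut_total), rep("water", n_water_total)),
      species = c(g_species, rep("", n_water_total)),
      ecotype = c(p$ecotypes[match(g_species, p$species)],
                  rep("", n_water_total)),
      site = c(grid$site[g_unit], grid$site[w_unit]),
      year = c(grid$year[g_unit], grid$year[w_unit]),
      weight_g = c(weight, rep(NA_real_, n_water_total)),
      length_cm = c(len, rep(NA_real_, n_water_total)),
      stringsAsFactors = FALSE))

    community <- community_structure(data.frame(
      species = p$species,
      count = pmax(1L, as.integer(round(stats::rlnorm(n_sp, log(20), 0.6)))),
      stringsAsFactors = FALSE))

    truth <- list(
      status = data.frame(sample_id = colnames(gut), true_status = g_status,
                          stringsAsFactors = FALSE),
      baselines = stats::setNames(p$baselines, p$species),
      core_microhi = stats::setNames(h_core, p$species),
      beta = p$beta,
      key_taxa = keys,
      env_microhi = stats::setNames(p$env_microhi, unit_names),
      key_water_abundance = key_water)

    out <- list(gut = abundance_table(gut, p$level),
                water = abundance_table(water, p$level),
                map = map, meta = meta, community = community,
                taxonomy = taxonomy, truth = truth, params = p)
    class(out) <- "microhi_simulation"
    out
  })
}

#' @export
print.microhi_simulation <- function(x, ...) {
  cat(sprintf("microhi_simulation: %d gut + %d water samples, %d taxa, %d species\n",
              ncol(x$gut), ncol(x$water), nrow(x$gut), length(x$params$species)))
  cat(sprintf("  true dysbiotic: %d (%.0f%%); key taxa: %s\n",
              sum(x$truth$status$true_status == "unhealthy"),
              100 * mean(x$truth$status$true_status == "unhealthy"),
              paste(x$truth$key_taxa, collapse = ", ")))
  invisible(x)
}

#' Write all tables of a simulated cohort to a directory
#'
#' Emits `gut.tsv`, `water.tsv`, `phenotypes.tsv`, `metadata.tsv`,
#' `community.tsv`, `taxonomy.tsv` and `ground_truth.tsv` in the formats
#' the readers of this package expect.
#'
#' @param sim a `microhi_simulation`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_table(sim$gut, file.path(dir, "gut.tsv"))
  write_abundance_table(sim$water, file.path(dir, "water.tsv"))
  write_tsv_strict(as.data.frame(sim$map), file.path(dir, "phenotypes.tsv"))
  write_tsv_strict(as.data.frame(sim$meta), file.path(dir, "metadata.tsv"))
  write_tsv_strict(as.data.frame(sim$community),
                   file.path(dir, "community.tsv"))
  write_tsv_strict(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv_strict(sim$truth$status, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
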