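#' Scenario configuration for the synthetic transect generator
#'
#' Defines a latitudinal ocean transect (stations, depths, size
#' fractions), a tropical-peaked Gaussian temperature profile, a regional
#' lognormal metacommunity on a simulated phylogeny with Brownian (hence
#' phylogenetically conserved) temperature niches, and the
#' community-assembly regime. Regimes fix the assembly knobs to produce a
#' known dominant mechanism:
#'
#' * `"selection"`: narrow thermal niche filter (`selection_width` 2 deg
#'   C), unlimited dispersal, local communities comparable in size to the
#'   niche-qualified pool (J = 150) so that ecologically equivalent taxa
#'   turn over between samples, and a weak thermal contrast along the
#'   transect (3-13 deg C, as in a mesopelagic section) — selection then
#'   expresses as homogeneous selection among thermally similar stations.
#' * `"dispersal_limitation"`: no niche filter, regionally perturbed
#'   metacommunity pools mixed over a short exponential distance kernel —
#'   compositional turnover without phylogenetic turnover.
#' * `"neutral_drift"`: no filter, unlimited dispersal, small local
#'   communities (`community_size` 500, sequenced exhaustively) — sampling
#'   noise dominates.
#' * `"mixed"`: intermediate values of all three knobs.
#'
#' @param regime One of `"selection"`, `"dispersal_limitation"`,
#'   `"neutral_drift"`, `"mixed"`.
#' @param n_stations Number of stations along the transect (default 26).
#' @param n_depths Number of sampling depths per station (default 8;
#'   depths 20-500 m, epipelagic and upper mesopelagic).
#' @param size_fractions Size-fraction labels replicated at every
#'   station/depth.
#' @param latitude_range Transect extent in degrees latitude.
#' @param temp_peak,temp_floor,temp_width Gaussian temperature profile:
#'   equatorial surface peak, polar floor (deg C) and width (deg
#'   latitude).
#' @param n_taxa Number of ASVs / tree tips.
#' @param meta_meanlog,meta_sdlog Lognormal regional abundance
#'   distribution.
#' @param brownian_rate Niche-trait variance per unit branch length (the
#'   tree has unit depth, so also the expected tip variance).
#' @param selection_width Thermal niche-filter SD in deg C (`Inf`
#'   disables filtering); set by the regime when `NULL`.
#' @param dispersal_scale E-folding distance (km) of source-pool mixing
#'   (`Inf` = unlimited); set by the regime when `NULL`.
#' @param community_size Individuals per local community (J); set by the
#'   regime when `NULL`.
#' @param read_depth Sequencing reads per sample; capped at
#'   `community_size`.
#' @param n_regions Number of contiguous station regions holding perturbed
#'   metacommunity pools (dispersal-limitation regime).
#' @param guild_delta Thermal displacement (deg C) applied to one deep
#'   clade of the tree (the clade whose size is closest to
#'   `guild_fraction` of all tips), emulating an anciently diverged
#'   cold-adapted guild; 0 disables it. Set by the regime when `NULL`.
#' @param guild_fraction Target relative size of the displaced guild
#'   clade.
#' @param lottery_sd SD of a per-sample lognormal colonization lottery
#'   multiplying the sampling weights (0 disables it); set by the regime
#'   when `NULL`. Emulates patchy bloom/colonization dynamics that let
#'   ecologically equivalent taxa replace each other between samples.
#' @param abundance_conservatism Fraction of the log-abundance variance
#'   that is phylogenetically conserved (Brownian on the tree), the rest
#'   idiosyncratic; related ecotypes then have similar regional
#'   abundances.
#' @param region_pool_sd Lognormal SD of the per-region pool perturbation.
#' @param seed RNG seed for the whole scenario.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(regime = c("selection", "dispersal_limitation",
                                       "neutral_drift", "mixed"),
                            n_stations = 26, n_depths = 8,
                            size_fractions = c("FL_0.2_3", "PA_3_8", "PA_gt8"),
                            latitude_range = c(-55, 55),
                            temp_peak = 29, temp_floor = 2, temp_width = 20,
                            n_taxa = 200,
                            meta_meanlog = 0, meta_sdlog = 1.5,
                            brownian_rate = 50,
                            selection_width = NULL,
                            dispersal_scale = NULL,
                            community_size = NULL,
                            read_depth = 8000,
                            n_regions = 5, region_pool_sd = 1.5,
                            abundance_conservatism = 0,
                            lottery_sd = NULL,
                            guild_delta = NULL, guild_fraction = 0.35,
                            seed = 1) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    selection = list(sw = 2, ds = Inf, J = 150, pool_sd = 0,
                     peak = 10, floor = 2, lottery = 1, sdlog = 0.8,
                     rate = 2, guild = -12),
    dispersal_limitation = list(sw = Inf, ds = 500, J = 1e5,
                                pool_sd = region_pool_sd, peak = temp_peak,
                                floor = temp_floor, lottery = 0,
                                sdlog = meta_sdlog, rate = brownian_rate,
                                guild = 0),
    neutral_drift = list(sw = Inf, ds = Inf, J = 500, pool_sd = 0,
                         peak = temp_peak, floor = temp_floor, lottery = 0,
                         sdlog = meta_sdlog, rate = brownian_rate, guild = 0),
    mixed = list(sw = 6, ds = 3000, J = 1e4, pool_sd = region_pool_sd,
                 peak = temp_peak, floor = temp_floor, lottery = 0,
                 sdlog = meta_sdlog, rate = brownian_rate, guild = 0)
  )
  if (is.null(selection_width)) selection_width <- defaults$sw
  if (is.null(dispersal_scale)) dispersal_scale <- defaults$ds
  if (is.null(community_size)) community_size <- defaults$J
  if (regime != "dispersal_limitation" && missing(region_pool_sd)) {
    region_pool_sd <- defaults$pool_sd
  }
  if (missing(temp_peak)) temp_peak <- defaults$peak
  if (missing(temp_floor)) temp_floor <- defaults$floor
  if (missing(meta_sdlog)) meta_sdlog <- defaults$sdlog
  if (missing(brownian_rate)) brownian_rate <- defaults$rate
  if (is.null(guild_delta)) guild_delta <- defaults$guild
  if (is.null(lottery_sd)) lottery_sd <- defaults$lottery
  if (n_stations < 1 || n_depths < 1 || n_taxa < 2) abort("All sizes must be >= 1.")
  if (selection_width <= 0) abort("`selection_width` must be positive.")
  read_depth <- min(read_depth, community_size)
  structure(list(
    regime = regime, n_stations = n_stations, n_depths = n_depths,
    size_fractions = size_fractions, latitude_range = latitude_range,
    temp_peak = temp_peak, temp_floor = temp_floor, temp_width = temp_width,
    n_taxa = n_taxa, meta_meanlog = meta_meanlog, meta_sdlog = meta_sdlog,
    abundance_conservatism = abundance_conservatism,
    lottery_sd = lottery_sd,
    guild_delta = guild_delta, guild_fraction = guild_fraction,
    brownian_rate = brownian_rate, selection_width = selection_width,
    dispersal_scale = dispersal_scale, community_size = community_size,
    read_depth = read_depth, n_regions = n_regions,
    region_pool_sd = region_pool_sd, seed = seed
  ), class = "scenario_config")
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' @param n_taxa Number of tips.
#' @param birth_rate,death_rate Speciation and extinction rates
#'   (`birth_rate > death_rate >= 0`).
#' @param seed Optional RNG seed.
#' @return An ultrametric `phylo` tree rescaled to unit crown depth, tips
#'   labelled `ASV_001`, ...
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, death_rate = 0, seed = NULL) {
  if (death_rate < 0 || birth_rate <= death_rate) {
    abort("Need `birth_rate` > `death_rate` >= 0.")
  }
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = death_rate))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("ASV_%03d", seq_len(n_taxa))
  tree
}

#' Simulate Brownian niche traits on a tree
#'
#' Brownian motion with variance `rate` per unit branch length starting
#' from `root_value`; close relatives receive similar niches, the
#' phylogenetic-signal precondition of the assembly framework.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param rate Trait variance per unit branch length (deg C squared).
#' @param root_value Trait value at the root (deg C).
#' @param seed Optional RNG seed.
#' @return A tibble with `asv_id`, `trait`.
#' @export
simulate_traits <- function(tree, rate, root_value = 18, seed = NULL) {
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  tr <- with_seed(seed, ape::rTraitCont(tree, model = "BM",
                                        sigma = sqrt(rate),
                                        root.value = root_value))
  tibble::tibble(asv_id = tree$tip.label, trait = as.numeric(tr[tree$tip.label]))
}

# Surface temperature profile: Gaussian in latitude with a polar floor.
surface_temperature <- function(lat, cfg) {
  cfg$temp_floor + (cfg$temp_peak - cfg$temp_floor) *
    exp(-lat^2 / (2 * cfg$temp_width^2))
}

# Temperature decays with depth towards a 4 deg C deep-ocean value.
depth_temperature <- function(t_surface, depth) {
  pmax(4 + (t_surface - 4) * exp(-depth / 300), 1)
}

sample_depths <- function(n_depths) {
  full <- c(20, 40, 60, 80, 100, 200, 300, 500)
  if (n_depths <= length(full)) full[seq_len(n_depths)] else
    round(seq(20, 500, length.out = n_depths))
}

# Tips of the internal clade whose size is closest to `frac` of all tips.
guild_clade <- function(tree, frac) {
  n <- length(tree$tip.label)
  sizes <- vapply((n + 2):(n + tree$Nnode), function(nd) {
    length(ape::extract.clade(tree, nd)$tip.label)
  }, integer(1))
  nd <- ((n + 2):(n + tree$Nnode))[which.min(abs(sizes / n - frac))]
  ape::extract.clade(tree, nd)$tip.label
}

province_of <- function(lat) {
  cut(lat, breaks = c(-90, -45, -23, 0, 23, 45, 90),
      labels = c("SANT", "SPSG_S", "PEQD_S", "PEQD_N", "NPSG", "PSAG"))
}

#' Assemble synthetic communities along the transect
#'
#' For each sample at temperature E, taxon i enters the local community
#' with weight proportional to `pool_i * exp(-(z_i - E)^2 / (2
#' selection_width^2))`, where the pool mixes regional metacommunities
#' through an exponential distance kernel. The local community is a
#' multinomial draw of `community_size` individuals; reads are a
#' multinomial draw of `read_depth` from the community.
#'
#' @param cfg A [scenario_config()].
#' @param tree Tree from [simulate_tree()] (simulated from `cfg` when
#'   `NULL`).
#' @param traits Trait tibble from [simulate_traits()] (simulated when
#'   `NULL`).
#' @return A `synthetic_dataset` list: `$counts`, `$metadata`, `$tree`,
#'   `$traits`, `$config`.
#' @export
assemble_communities <- function(cfg, tree = NULL, traits = NULL) {
  with_seed(cfg$seed, {
    if (is.null(tree)) tree <- simulate_tree(cfg$n_taxa)
    if (is.null(traits)) {
      traits <- simulate_traits(tree, cfg$brownian_rate)
      if (cfg$guild_delta != 0) {
        guild <- guild_clade(tree, cfg$guild_fraction)
        traits$trait[traits$asv_id %in% guild] <-
          traits$trait[traits$asv_id %in% guild] + cfg$guild_delta
      }
    }
    if (!setequal(tree$tip.label, traits$asv_id)) {
      abort("Tree tips and trait ASVs do not match.")
    }
    z <- traits$trait[match(tree$tip.label, traits$asv_id)]
    p <- length(z)
    lat <- seq(cfg$latitude_range[1], cfg$latitude_range[2],
               length.out = cfg$n_stations)
    lon <- seq(-175, -135, length.out = cfg$n_stations)
    depths <- sample_depths(cfg$n_depths)
    # Regional log-abundances: partly phylogenetically conserved (related
    # ecotypes have similar regional abundance), partly idiosyncratic.
    a <- cfg$abundance_conservatism
    bm_std <- as.numeric(ape::rTraitCont(tree, model = "BM", sigma = 1,
                                         root.value = 0))[seq_len(p)]
    m <- exp(cfg$meta_meanlog + cfg$meta_sdlog *
               (sqrt(a) * bm_std + sqrt(1 - a) * stats::rnorm(p)))
    # regional pools: contiguous latitude blocks with perturbed abundances
    region <- as.integer(cut(seq_len(cfg$n_stations),
                             breaks = cfg$n_regions, labels = FALSE))
    pools <- vapply(seq_len(cfg$n_regions), function(r) {
      if (cfg$region_pool_sd > 0) {
        m * exp(stats::rnorm(p, 0, cfg$region_pool_sd))
      } else m
    }, numeric(p))                      # taxa x regions
    region_center <- vapply(seq_len(cfg$n_regions), function(r) {
      mean(lat[region == r])
    }, numeric(1))
    region_center_lon <- vapply(seq_len(cfg$n_regions), function(r) {
      mean(lon[region == r])
    }, numeric(1))
    grid <- tidyr::expand_grid(station = seq_len(cfg$n_stations),
                               depth = depths,
                               size_fraction = cfg$size_fractions)
    n_samples <- nrow(grid)
    counts <- matrix(0L, n_samples, p)
    meta <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      st <- grid$station[s]
      t_surf <- surface_temperature(lat[st], cfg)
      temp <- depth_temperature(t_surf, grid$depth[s])
      if (is.infinite(cfg$dispersal_scale)) {
        pool <- rowMeans(pools)
      } else {
        dist_km <- haversine_km(lat[st], lon[st], region_center, region_center_lon)
        kern <- exp(-dist_km / cfg$dispersal_scale)
        pool <- as.numeric(pools %*% (kern / sum(kern)))
      }
      filt <- if (is.infinite(cfg$selection_width)) 1 else
        exp(-(z - temp)^2 / (2 * cfg$selection_width^2))
      wgt <- pool * filt
      if (cfg$lottery_sd > 0) {
        wgt <- wgt * exp(stats::rnorm(p, 0, cfg$lottery_sd))
      }
      if (sum(wgt) <= 0) wgt <- pool
      community <- stats::rmultinom(1, cfg$community_size, wgt)[, 1]
      reads <- stats::rmultinom(1, cfg$read_depth, community)[, 1]
      counts[s, ] <- as.integer(reads)
      no3 <- pmax(0, 30 * (1 - temp / cfg$temp_peak) + stats::rnorm(1, 0, 1))
      meta[[s]] <- tibble::tibble(
        sample_id = sprintf("St%02d_D%03d_%s", st, grid$depth[s],
                            grid$size_fraction[s]),
        latitude = lat[st], longitude = lon[st], depth = grid$depth[s],
        size_fraction = grid$size_fraction[s],
        layer = if (grid$depth[s] <= 100) "epipelagic" else "mesopelagic",
        province = as.character(province_of(lat[st])),
        temperature = temp,
        NO_x = no3,
        oxygen = pmax(0, 350 - 5 * temp - 0.2 * grid$depth[s] + stats::rnorm(1, 0, 5)),
        salinity = 34 + 0.05 * temp + stats::rnorm(1, 0, 0.1),
        chlorophyll = pmax(0.01, exp(stats::rnorm(1, -1 + temp / 30, 0.3)))
      )
    }
    metadata <- dplyr::bind_rows(meta)
    rownames(counts) <- metadata$sample_id
    colnames(counts) <- tree$tip.label
    structure(list(counts = count_tibble(counts), metadata = metadata,
                   tree = tree, traits = traits, config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic transect dataset (regime:", x$config$regime, ")\n")
  cat(" ", nrow(x$metadata), "samples,", x$config$n_taxa, "ASVs,",
      x$config$n_stations, "stations x", x$config$n_depths, "depths x",
      length(x$config$size_fractions), "size fractions\n")
  invisible(x)
}

#' Generate a synthetic dataset and optionally write it to disk
#'
#' One call produces the complete fixture set (counts TSV, metadata TSV,
#' Newick tree, traits TSV, config YAML echo), byte-identical under the
#' same seed.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return The `synthetic_dataset`, invisibly when writing.
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  ds <- assemble_communities(cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(ds$counts, file.path(dir, "counts.tsv"), sidecar = FALSE)
    write_sample_metadata(ds$metadata, file.path(dir, "metadata.tsv"))
    ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
    readr::write_tsv(ds$traits, file.path(dir, "traits.tsv"), progress = FALSE)
    cfg_out <- ds$config
    class(cfg_out) <- NULL
    cfg_out <- lapply(cfg_out, function(v) if (is.numeric(v) && any(is.infinite(v))) "Inf" else v)
    yaml::write_yaml(cfg_out, file.path(dir, "config.yml"))
    return(invisible(ds))
  }
  ds
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file with `scenario_config()` fields.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(v) if (identical(v, "Inf")) Inf else v)
  do.call(scenario_config, raw)
}
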