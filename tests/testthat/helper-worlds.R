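# shared fixtures, built lazily and cached for the session

.fs_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fs_test_cache)) {
    assign(key, force(expr), .fs_test_cache)
  }
  get(key, .fs_test_cache)
}

small_world <- function() {
  cached("small_world",
         generate_world(world_config(regions = c("BRA", "EUR", "SSA")),
                        seed = 42))
}

two_region_world <- function() {
  cached("two_region_world",
         generate_world(world_config(regions = c("BRA", "EUR")), seed = 7))
}

default_world <- function() {
  cached("default_world", generate_world(world_config(), seed = 1))
}

ref_run <- function() {
  cached("ref_run", run_scenario(default_world()))
}

level_run <- function(level) {
  key <- paste0("run_L", round(level * 100))
  cached(key, run_scenario(default_world(), scenario_spec(level = level),
                           ref = ref_run()))
}

small_ref_run <- function() {
  cached("small_ref_run", run_scenario(small_world()))
}

small_level_run <- function(level) {
  key <- paste0("small_run_L", round(level * 100))
  cached(key, run_scenario(small_world(), scenario_spec(level = level),
                           ref = small_ref_run()))
}

# a minimal hand-built single-market instance (one region, one crop):
# inverse demand p = a - b q, flat marginal cost c, optional land cap
toy_instance <- function(a = 10, b = 1, c = 4, cropland = 1e6,
                         yield = 1) {
  regs <- "R1"; crops <- "wheat"; animals <- character(0)
  land <- matrix(0, 1, length(fs_land_classes()),
                 dimnames = list(regs, fs_land_classes()))
  land[, "cropland"] <- cropland
  structure(list(
    year = 2020, regions = regs, commodities = crops,
    crops = crops, animals = animals,
    demand_a = matrix(a, 1, 1, dimnames = list(regs, crops)),
    demand_b = matrix(b, 1, 1, dimnames = list(regs, crops)),
    supply_c = matrix(c, 1, 1, dimnames = list(regs, crops)),
    supply_d = matrix(0, 1, 1, dimnames = list(regs, crops)),
    yield = matrix(yield, 1, 1, dimnames = list(regs, crops)),
    grass_req = matrix(0, 1, 0, dimnames = list(regs, NULL)),
    feed_conv = matrix(0, 1, 0, dimnames = list(regs, NULL)),
    feed_share = matrix(0, 1, 0, dimnames = list(crops, NULL)),
    trade_cost_exp = matrix(1, 1, 1, dimnames = list(regs, crops)),
    trade_cost_imp = matrix(1, 1, 1, dimnames = list(regs, crops)),
    trade_quad = 1e-3,
    conv_cost = matrix(1e3, 1, 5,
                       dimnames = list(regs,
                                       c("n2c", "n2g", "g2c", "a2c",
                                         "a2g"))),
    conv_quad = 1,
    land = land,
    fixed_food_demand = NULL,
    alt_crop_demand = matrix(0, 1, 1, dimnames = list(regs, crops)),
    import_caps = matrix(Inf, 1, 1, dimnames = list(regs, crops))
  ), class = "fs_instance")
}

# two regions, one commodity, flat marginal costs c1/c2, demand p = 10 - q in
# both, one-way trade cost on the export leg
two_region_instance <- function(c1 = 2, c2 = 6, trade_cost = 1) {
  regs <- c("R1", "R2"); crops <- "wheat"; animals <- character(0)
  land <- matrix(0, 2, length(fs_land_classes()),
                 dimnames = list(regs, fs_land_classes()))
  land[, "cropland"] <- 1e6
  m1 <- function(v) matrix(v, 2, 1, dimnames = list(regs, crops))
  structure(list(
    year = 2020, regions = regs, commodities = crops,
    crops = crops, animals = animals,
    demand_a = m1(10), demand_b = m1(1),
    supply_c = m1(c(c1, c2)), supply_d = m1(0),
    yield = m1(1),
    grass_req = matrix(0, 2, 0, dimnames = list(regs, NULL)),
    feed_conv = matrix(0, 2, 0, dimnames = list(regs, NULL)),
    feed_share = matrix(0, 1, 0, dimnames = list(crops, NULL)),
    trade_cost_exp = m1(trade_cost), trade_cost_imp = m1(0),
    trade_quad = 1e-3,
    conv_cost = matrix(1e3, 2, 5,
                       dimnames = list(regs,
                                       c("n2c", "n2g", "g2c", "a2c",
                                         "a2g"))),
    conv_quad = 1,
    land = land,
    fixed_food_demand = NULL,
    alt_crop_demand = matrix(0, 2, 1, dimnames = list(regs, crops)),
    import_caps = matrix(Inf, 2, 1, dimnames = list(regs, crops))
  ), class = "fs_instance")
}

# independent brute-force oracle for the two-region instance: grid search
# over (q1, q2, t) where t is the flow R1 -> R2, welfare evaluated directly
brute_force_welfare <- function(c1 = 2, c2 = 6, trade_cost = 1,
                                coarse = 0.05, fine = 0.01) {
  welfare <- function(q1, q2, t) {
    x1 <- q1 + t; x2 <- q2 - t
    ifelse(x2 < 0, -Inf,
           10 * q1 - q1^2 / 2 + 10 * q2 - q2^2 / 2 -
             c1 * x1 - c2 * x2 - trade_cost * t)
  }
  search <- function(q1s, q2s, ts) {
    best <- c(-Inf, 0, 0, 0)
    for (t in ts) {
      g <- expand.grid(q1 = q1s, q2 = q2s)
      w <- welfare(g$q1, g$q2, t)
      i <- which.max(w)
      if (w[i] > best[1]) best <- c(w[i], g$q1[i], g$q2[i], t)
    }
    best
  }
  b <- search(seq(0, 10, coarse), seq(0, 10, coarse), seq(0, 10, coarse))
  lo <- function(v) max(0, v - coarse); hi <- function(v) min(10, v + coarse)
  b <- search(seq(lo(b[2]), hi(b[2]), fine), seq(lo(b[3]), hi(b[3]), fine),
              seq(lo(b[4]), hi(b[4]), fine))
  list(welfare = b[1], q1 = b[2], q2 = b[3], t = b[4])
}
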