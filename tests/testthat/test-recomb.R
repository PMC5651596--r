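# Rate computation on intervals: interpolation, masking, binned summaries.

test_that("cumulative cM interpolates linearly and clamps outside markers", {
  m <- tiny_map()
  expect_equal(cumulative_cm_at(m, "chr1", c(1000, 2000, 4000)),
               c(0, 0.01, 0.05))                       # marker identity
  expect_equal(cumulative_cm_at(m, "chr1", 3000), 0.03)  # hand interpolation
  expect_equal(cumulative_cm_at(m, "chr1", c(0, 999)), c(0, 0))  # clamp left
  expect_equal(cumulative_cm_at(m, "chr1", 1e6), 0.05)           # clamp right
  expect_error(cumulative_cm_at(m, "chr9", 1), "absent")
})

test_that("interval rate matches hand computation and flags no coverage", {
  m <- tiny_map()
  # cum at 1500 = 0.005, at 3000 = 0.03; 0.025 cM over 1500 bp
  r <- interval_rate(m, tibble::tibble(chrom = "chr1", start = 1500, end = 3000))
  expect_equal(r$rate, 0.025 / (1500 / 1e6), tolerance = 1e-12)
  # whole marker range telescopes to total cM over total Mb
  r2 <- interval_rate(m, tibble::tibble(chrom = "chr1", start = 1000, end = 4000))
  expect_equal(r2$rate, 0.05 / (3000 / 1e6))
  # entirely outside the mapped range: 0 with the no-coverage flag
  r3 <- interval_rate(m, tibble::tibble(chrom = "chr1", start = 10000, end = 20000))
  expect_equal(r3$rate, 0)
  expect_true(r3$no_coverage)
  expect_false(r$no_coverage)
})

test_that("constant-rate map gives the constant for any interval", {
  m <- genetic_map(tibble::tibble(chrom = "chr1", pos = seq(0, 1e6, 1e4),
                                  cum_cm = seq(0, 1e6, 1e4) * 2.5 / 1e6))
  set.seed(1)
  s <- sort(sample(0:9e5, 20))
  iv <- tibble::tibble(chrom = "chr1", start = s, end = s + 1e4)
  expect_equal(interval_rate(m, iv)$rate, rep(2.5, 20), tolerance = 1e-9)
})

test_that("interval rate agrees with the marker-sum oracle on random maps", {
  set.seed(99)
  for (rep in 1:5) {
    pos <- sort(sample(0:5e5, 40))
    cum <- cumsum(c(0, runif(39, 0, 0.05)))
    m <- genetic_map(tibble::tibble(chrom = "chr1", pos = pos, cum_cm = cum))
    s <- sample(0:4e5, 40)
    e <- s + sample(100:1e5, 40, replace = TRUE)
    got <- interval_rate(m, tibble::tibble(chrom = "chr1", start = s, end = e))$rate
    want <- vapply(seq_along(s),
                   function(i) oracle_interval_rate(m, "chr1", s[i], e[i]),
                   numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("rate is additive over adjacent intervals", {
  scn <- small_scenario()
  set.seed(3)
  s <- sample(0:4e6, 200)
  mid <- s + sample(1e3:2e5, 200, replace = TRUE)
  e <- mid + sample(1e3:2e5, 200, replace = TRUE)
  ra <- interval_rate(scn$map, tibble::tibble(chrom = "chr1", start = s, end = mid))$rate
  rb <- interval_rate(scn$map, tibble::tibble(chrom = "chr1", start = mid, end = e))$rate
  rab <- interval_rate(scn$map, tibble::tibble(chrom = "chr1", start = s, end = e))$rate
  weighted <- (ra * (mid - s) + rb * (e - mid)) / (e - s)
  expect_equal(rab, weighted, tolerance = 1e-9)
  expect_true(all(rab >= 0))
})

test_that("masked rate excludes masked bases", {
  m <- tiny_map()
  # empty mask: identical to interval_rate
  iv <- tibble::tibble(chrom = "chr1", start = 1500, end = 3000)
  r0 <- interval_rate_masked(m, iv, tibble::tibble(chrom = character(),
                                                   start = numeric(),
                                                   end = numeric()))
  expect_equal(r0$rate, interval_rate(m, iv)$rate)
  # two-segment landscape 1 then 3 cM/Mb; masking the hot half leaves 1
  m2 <- genetic_map(tibble::tibble(chrom = "chr1", pos = c(0, 1e6, 2e6),
                                   cum_cm = c(0, 1, 4)))
  r1 <- interval_rate_masked(m2, tibble::tibble(chrom = "chr1", start = 0, end = 2e6),
                             tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6))
  expect_equal(r1$rate, 1.0, tolerance = 1e-12)
  # constant map: any partial mask leaves the constant
  mc <- genetic_map(tibble::tibble(chrom = "chr1", pos = c(0, 1e6), cum_cm = c(0, 2)))
  r2 <- interval_rate_masked(mc, tibble::tibble(chrom = "chr1", start = 0, end = 1e6),
                             tibble::tibble(chrom = "chr1",
                                            start = c(1e5, 5e5), end = c(2e5, 6e5)))
  expect_equal(r2$rate, 2.0, tolerance = 1e-12)
  # fully masked interval is flagged
  r3 <- interval_rate_masked(mc, tibble::tibble(chrom = "chr1", start = 100, end = 200),
                             tibble::tibble(chrom = "chr1", start = 0, end = 1000))
  expect_true(r3$fully_masked)
  expect_true(is.na(r3$rate))
})

test_that("distance-binned means use the sd * 1.96 / 10 band", {
  m <- genetic_map(tibble::tibble(chrom = "chr1", pos = c(0, 1e6), cum_cm = c(0, 2)))
  # identical constant rate: every occupied bin has mean 2, zero width band
  l <- point_links("chr1", c(1e4, 2e4, 3e4), c(3e4, 5e4, 9e4))
  rb <- mean_rate_by_distance(l, m, n_bins = 4)
  occ <- rb[rb$n > 0, ]
  expect_equal(occ$mean_rate, rep(2, nrow(occ)))
  expect_equal(occ$ci_half, rep(0, nrow(occ)))  # singleton sd defined as 0
  expect_true(all(rb$n[rb$n == 0] == 0))      # empty bins reported
  expect_true(all(is.na(rb$mean_rate[rb$n == 0])))
  # two links in one bin with rates 1 and 3: mean 2, half-width sd * 0.196
  m2 <- genetic_map(tibble::tibble(chrom = "chr1", pos = c(0, 2e4, 4e4, 1e6),
                                   cum_cm = c(0, 0.02, 0.08, 0.08 + 0.96 * 3)))
  # spans [0, 2e4) and [2e4, 4e4): rates exactly 1 and 3, same distance bin
  l2 <- point_links("chr1", c(0, 2e4), c(2e4 - 1, 4e4 - 1))
  rb2 <- mean_rate_by_distance(l2, m2, n_bins = 1)
  row <- rb2[rb2$n == 2, ]
  expect_equal(row$mean_rate, 2)
  expect_equal(row$ci_half, sd(c(1, 3)) * 1.96 / 10)
})

test_that("hotspot density counts midpoints per kb", {
  iv <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5)
  none <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  expect_equal(hotspot_density(iv, none), 0)
  hs <- tibble::tibble(chrom = "chr1", start = c(1e4, 5e4, 2e5), end = c(1e4, 5e4, 2e5) + 2000)
  expect_equal(hotspot_density(iv, hs), 2 / 100)  # 2 midpoints in 100 kb
  # a threshold partitions any link set
  scn <- small_scenario()
  dens <- hotspot_density(tibble::tibble(chrom = scn$links$chrom,
                                         start = scn$links$span_start,
                                         end = scn$links$span_end), scn$hotspots)
  expect_equal(sum(dens < 0.005) + sum(dens >= 0.005), nrow(scn$links))
})
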