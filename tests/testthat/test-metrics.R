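# Region map used by the worked-example metrics: countries 1,2 -> Europe
# ("X" role), countries 3,4 -> Asia ("Y" role).
worked_map <- c("1" = "Europe", "2" = "Europe", "3" = "Asia", "4" = "Asia")

test_that("total connections sums edge weights", {
  net <- build_network(worked_example())
  expect_equal(total_connections(net), 6L)
  expect_equal(total_connections(build_network(worked_example()[0, ])), 0L)
  # r copies of one k-country study -> r * C(k,2)
  r <- 3L; k <- 5L
  reg <- trial_registry(sprintf("S%d", 1:r), rep(2000L, r),
                        rep(list(sprintf("C%d", 1:k)), r))
  expect_equal(total_connections(build_network(reg)), r * choose(k, 2))
})

test_that("country totals and shares match hand computation and oracle", {
  net <- build_network(worked_example())
  ct <- country_connection_totals(net)
  expect_equal(stats::setNames(ct$total, ct$country),
               c("2" = 4L, "3" = 4L, "1" = 2L, "4" = 2L))
  expect_equal(stats::setNames(ct$share, ct$country),
               c("2" = 1/3, "3" = 1/3, "1" = 1/6, "4" = 1/6))
  expect_equal(sum(ct$share), 1)
  expect_equal(ct$country[1:2], c("2", "3"))   # ties broken by name
  # single-edge network: both countries share 1/2
  single <- build_network(trial_registry("S", 2000L, list(c("A", "B"))))
  expect_equal(country_connection_totals(single)$share, c(0.5, 0.5))
  # random fixture vs brute-force incidence sums
  set.seed(601)
  reg <- random_registry(30, p_single = 0)
  net2 <- build_network(reg)
  oracle <- brute_force_network(reg)
  ct2 <- country_connection_totals(net2)
  expect_equal(stats::setNames(ct2$total, ct2$country)[oracle$nodes$country],
               stats::setNames(oracle$nodes$size, oracle$nodes$country))
})

test_that("region totals respect the attribution policies", {
  net <- build_network(worked_example())
  half <- region_connection_totals(net, worked_map, "endpoint_half")
  expect_equal(stats::setNames(half$mass, half$region),
               c(Asia = 3.0, Europe = 3.0))
  expect_equal(half$share, c(0.5, 0.5))
  full <- region_connection_totals(net, worked_map, "endpoint_full")
  expect_equal(sum(full$share), 1)
  expect_equal(stats::setNames(half$mass, half$region),
               stats::setNames(full$mass / 2, full$region))
  # all countries in one region -> share 1 under both policies
  mono <- c("1" = "Europe", "2" = "Europe", "3" = "Europe", "4" = "Europe")
  for (pol in c("endpoint_half", "endpoint_full")) {
    rt <- region_connection_totals(net, mono, pol)
    expect_equal(rt$share, 1)
  }
  # random fixture: identity half = full/2 and closure under both policies
  set.seed(602)
  reg <- random_registry(40, p_single = 0)
  net2 <- build_network(reg)
  rmap <- toy_region_map()
  h <- region_connection_totals(net2, rmap, "endpoint_half")
  f <- region_connection_totals(net2, rmap, "endpoint_full")
  expect_equal(h$mass, f$mass / 2)
  expect_equal(sum(h$share), 1, tolerance = 1e-9)
  expect_equal(sum(f$share), 1, tolerance = 1e-9)
  # strict mode rejects unmapped countries
  expect_error(region_connection_totals(net2, rmap[-1], strict = TRUE),
               "not in region map")
})

test_that("cross-region share matches hand enumeration and edge cases", {
  net <- build_network(worked_example())
  expect_equal(cross_region_share(net, worked_map), 4 / 6)
  mono <- stats::setNames(rep("Europe", 4), as.character(1:4))
  expect_equal(cross_region_share(net, mono), 0)
  each_own <- stats::setNames(
    c("Europe", "Asia", "Africa", "Oceania"), as.character(1:4))
  expect_equal(cross_region_share(net, each_own), 1)
  expect_error(cross_region_share(build_network(worked_example()[0, ]),
                                  worked_map), "empty")
  # invariance under region relabeling (bijection)
  set.seed(603)
  reg <- random_registry(30, p_single = 0)
  net2 <- build_network(reg)
  rmap <- toy_region_map()
  relabeled <- stats::setNames(
    c(Europe = "Oceania", Asia = "Africa")[rmap], names(rmap))
  expect_equal(cross_region_share(net2, rmap),
               cross_region_share(net2, relabeled))
})

test_that("top edges rank by weight with canonical tie-break", {
  net <- build_network(worked_example())
  t1 <- top_edges(net, 1)
  expect_equal(t1$u, "2"); expect_equal(t1$v, "3")
  expect_equal(t1$weight, 2L)
  expect_equal(nrow(top_edges(net, 100)), 5L)
  expect_error(top_edges(net, 0), "k must be")
  # agreement with a full sort oracle
  set.seed(604)
  reg <- random_registry(40, p_single = 0)
  net2 <- build_network(reg)
  e <- net2$edges
  oracle <- e[order(-e$weight, e$u, e$v), , drop = FALSE][1:3, ]
  rownames(oracle) <- NULL
  expect_equal(top_edges(net2, 3), oracle)
})

test_that("participation report counts region-touching studies", {
  pr <- participation_report(worked_example(), worked_map)
  expect_equal(pr$region$n_studies, c(2L, 2L))   # both studies touch both
  expect_equal(pr$region$proportion, c(1, 1))
  one <- trial_registry("S", 2000L, list(c("France", "Germany")))
  pr2 <- participation_report(one, default_region_map())
  expect_equal(pr2$region$region, "Europe")
  expect_equal(pr2$region$proportion, 1)
  # random fixture vs brute-force membership scan
  set.seed(605)
  reg <- filter_multinational(random_registry(40))
  rmap <- toy_region_map()
  pr3 <- participation_report(reg, rmap)
  for (r in pr3$region$region) {
    expected <- sum(vapply(reg$countries,
                           function(cs) any(rmap[cs] == r), logical(1)))
    expect_equal(pr3$region$n_studies[pr3$region$region == r], expected)
  }
  for (cn in pr3$country$country) {
    expect_equal(pr3$country$n_studies[pr3$country$country == cn],
                 sum(vapply(reg$countries, function(cs) cn %in% cs,
                            logical(1))))
  }
  expect_true(all(pr3$region$n_studies <= nrow(reg)))
  expect_error(participation_report(random_registry(10), rmap),
               "multinational")
})

test_that("monotonicity: adding a study never decreases totals", {
  set.seed(606)
  base <- random_registry(20, p_single = 0)
  extra <- trial_registry("ZZZ", 2000L, list(c("C01", "C07", "C09")))
  grown <- rbind(base, extra)
  class(grown) <- c("trial_registry", "data.frame")
  n1 <- build_network(base); n2 <- build_network(grown)
  expect_gte(total_connections(n2), total_connections(n1))
  c1 <- country_connection_totals(n1); c2 <- country_connection_totals(n2)
  for (cn in c1$country) {
    expect_gte(c2$total[c2$country == cn], c1$total[c1$country == cn])
  }
})

test_that("edge-weight frequencies converge to the product of inclusion rates", {
  # countries A and B independently included in each of N studies with
  # probabilities pA and pB; weight(A,B)/N must approach pA*pB.
  set.seed(607)
  n <- 20000L; pa <- 0.3; pb <- 0.2
  ina <- stats::runif(n) < pa
  inb <- stats::runif(n) < pb
  cs <- lapply(seq_len(n), function(i) {
    c(if (ina[i]) "A", if (inb[i]) "B", "Z")  # Z keeps studies multinational
  })
  keep <- lengths(cs) >= 2L
  reg <- trial_registry(sprintf("S%05d", which(keep)), 2000L, cs[keep])
  net <- build_network(reg)
  w <- net$edges$weight[net$edges$u == "A" & net$edges$v == "B"]
  se <- sqrt(n * pa * pb * (1 - pa * pb))
  expect_lt(abs(w - n * pa * pb), 4 * se)
})

test_that("connectivity report writers produce sorted machine-readable files", {
  net <- build_network(worked_example())
  rep <- connectivity_report(net, worked_map, k = 3)
  dir <- tempfile()
  write_connectivity_report(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("country_totals.csv", "region_totals.csv", "top_edges.csv",
           "connectivity.json")))))
  js <- jsonlite::read_json(file.path(dir, "connectivity.json"))
  expect_equal(js$total_weight, 6L)
  expect_equal(js$cross_region_share, 4 / 6)
})
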