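# Generators, sweeps, reports, file I/O, CLI.

test_that("network generation is seed-deterministic and hits target w_av", {
  rec <- network_recipe("erdos-renyi", N = 50, density = 0.1,
                        weight = "uniform", target_w_av = 5, seed = 3)
  g1 <- generate_network(rec)
  g2 <- generate_network(rec)
  expect_identical(g1$M, g2$M)
  expect_equal(g1$w_av, 5, tolerance = 1e-9)
  expect_error(network_recipe("erdos-renyi", N = 0), "at least 1")

  sf <- generate_network(network_recipe("scale-free", N = 60, k = 2, seed = 8))
  expect_gt(sf$m, 0)
  expect_equal(sf$M, t(sf$M))                      # symmetrised attachment
  # heavier tail than a regular graph: max degree well above the median
  deg <- colSums(sf$M > 0)
  expect_gt(max(deg), 3 * median(deg))
})

test_that("commuter fixtures run through both UQ layers for N in 30/100/300", {
  for (N in c(30L, 100L, 300L)) {
    cn <- generate_commuter_network(N, seed = N)
    expect_equal(cn$distances, t(cn$distances))
    expect_true(all(diag(cn$distances) == 0))
    mod <- commuter_model(K = 10,
                          C = random_input("uniform", lower = 0.9, upper = 1.1,
                                           label = "C"),
                          distances = cn$distances, mode = "iid")
    st <- clt_statistics(mod, n_quad = 4)
    sur <- fit_tau_pce(st, cn$graph, order = 2)
    pr <- network_resilience_probability(sur)
    expect_gte(pr$value, 0); expect_lte(pr$value, 1)

    nd <- which.min(cn$graph$w_in)
    ns <- fit_node_apc(mod, cn$graph, nd, order = 2)
    np <- node_resilience_probability(ns, n_samples = 5e3, seed = 1)
    expect_gte(np$probability, 0); expect_lte(np$probability, 1)
  }
})

test_that("deterministic sweep steps from 0 to 1 at the bifurcation", {
  mod <- fix_model()
  g <- fix_graph(N = 30, w_av = 5)
  grid <- seq(6, 8, by = 0.25)
  res <- sweep_network_resilience(mod, g, grid)
  expect_equal(nrow(res), length(grid))
  det <- res[res$method == "deterministic", ]
  expect_true(all(det$probability %in% c(0, 1)))
  step_at <- det$w_av[which(diff(det$probability) == 1)]
  w_star <- critical_threshold(mod)$w_star
  expect_lt(abs(step_at - w_star), 0.25 + 1e-9)    # within one grid step
  expect_true(all(diff(det$probability) >= 0))
})

test_that("uncertain sweep gives calibrated probabilities near the threshold", {
  mod <- fix_model()
  g <- fix_graph(N = 30, w_av = 5)
  inputs <- fix_case_a_inputs()
  res <- sweep_network_resilience(mod, g, c(6.97), inputs, mode = "shared",
                                  order = 3, n_samples = 2e4, seed = 2)
  expect_equal(nrow(res), 2L)                      # grid x methods
  unc <- res[res$method == "uncertain-shared", ]
  expect_gt(unc$probability, 0.05)
  expect_lt(unc$probability, 0.95)                 # genuinely uncertain at w*
  res2 <- sweep_network_resilience(mod, g, c(6.97), inputs, mode = "shared",
                                   order = 3, n_samples = 2e4, seed = 2)
  expect_identical(res, res2)                      # end-to-end reproducibility

  # iid mode routes through the CLT + Hermite PCE machinery
  res_iid <- sweep_network_resilience(mod, g, c(7.5), inputs["C"],
                                      mode = "iid", order = 3, seed = 2)
  unc_iid <- res_iid[res_iid$method == "uncertain-iid", ]
  expect_gte(unc_iid$probability, 0); expect_lte(unc_iid$probability, 1)
})

test_that("order/accuracy report covers both method families coherently", {
  mod <- fix_case_a_model()
  g <- fix_vulnerable_graph()
  rep_ <- order_accuracy_report(mod, g, 1, orders = 1:3,
                                mc_sizes = c(100L, 400L), n_ref = 1000L,
                                n_prob = 2e4, seed = 7)
  expect_setequal(unique(rep_$method), c("apc", "mc"))
  expect_equal(nrow(rep_), 5L)
  expect_true(all(rep_$probability >= 0 & rep_$probability <= 1))
  expect_true(all(rep_$accuracy <= 1 + 1e-12))
  apc <- rep_[rep_$method == "apc", ]
  # order convergence within the reference's Monte Carlo noise
  expect_gte(apc$accuracy[3], apc$accuracy[1] - 0.05)
  expect_true(all(diff(apc$n_evals) > 0))          # cost grows with order
})

test_that("uncertainty specification files parse into random inputs", {
  dir <- tempfile(); dir.create(dir)
  samples_path <- file.path(dir, "c_samples.txt")
  set.seed(5)
  writeLines(format(rnorm(500, 1, 0.05), digits = 10), samples_path)
  spec_path <- file.path(dir, "unc.json")
  jsonlite::write_json(list(
    C = list(kind = "uniform", params = list(lower = 0.9, upper = 1.1)),
    E = list(samples_file = "c_samples.txt"),
    H = list(moments = c(1, 0, 1, 0, 3))), spec_path, auto_unbox = TRUE)
  inputs <- read_uncertainty(spec_path)
  expect_named(inputs, c("C", "E", "H"))
  expect_equal(inputs$C$kind, "uniform")
  expect_equal(inputs$E$kind, "samples")
  expect_length(inputs$E$spec$x, 500)
  expect_equal(raw_moments(inputs$H, 4)$values, c(1, 0, 1, 0, 3))
})

test_that("results tables round-trip as CSV and JSON with config echo", {
  tab <- data.frame(w_av = c(6, 7), probability = c(0.2, 0.9),
                    method = "apc")
  pcsv <- tempfile(fileext = ".csv")
  write_results(tab, pcsv)
  expect_equal(read.csv(pcsv), tab)
  pjson <- tempfile(fileext = ".json")
  write_results(tab, pjson, config = list(seed = 1))
  back <- jsonlite::read_json(pjson, simplifyVector = TRUE)
  expect_equal(back$config$seed, 1)
  expect_equal(back$results$probability, tab$probability)
})

test_that("CLI subcommands generate networks and curves", {
  dir <- tempfile(); dir.create(dir)
  net_path <- file.path(dir, "net.csv")
  g <- netres_cli(c("generate", "--family", "erdos-renyi", "--n", "40",
                    "--density", "0.15", "--target-wav", "6", "--seed", "4",
                    "--output", net_path))
  expect_true(file.exists(net_path))
  expect_equal(read_network(net_path, n_nodes = 40)$M, g$M)

  curve_path <- file.path(dir, "curve.csv")
  cc <- netres_cli(c("critical-curve", "--wav-grid", "6:8:1",
                     "--output", curve_path))
  got <- read.csv(curve_path)
  expect_equal(got$w_av, c(6, 7, 8))
  expect_equal(got$w_crit, cc$curve$w_crit, tolerance = 1e-12)

  expect_error(netres_cli(c("frobnicate")), "unknown subcommand")
  expect_error(netres_cli(c("generate", "oops")), "expected --flag")
})
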