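test_that("chip presets carry the published operating conditions", {
  odin <- chip_odin()
  expect_equal(odin$neurons_per_core, 256L)
  expect_equal(odin$n_cores, 1L)
  expect_equal(odin$e_sop_pj, 8.4)
  expect_equal(odin$f_clk_hz, 75e6)
  morphic <- chip_morphic()
  expect_equal(morphic$neurons_per_core, 512L)
  expect_equal(morphic$n_cores, 4L)
  expect_equal(morphic$e_sop_pj, 30)
  expect_equal(morphic$f_clk_hz, 55e6)
  expect_equal(odin$cycles_per_sop, 2L)
  expect_error(chip_model("x", 1, 1, e_sop_pj = -1, f_clk_hz = 1), "e_sop")
})

test_that("crossbar SOP accounting matches the published per-spike numbers", {
  branch <- spec_morphic_branch()
  # one input spike into the 512-neuron core hosting a 210-unit hidden
  # layer: 512 total, 210 useful
  s <- count_sops(branch, c(input = 1, layer1 = 0, layer2 = 0),
                  chip_morphic())
  expect_equal(s$total, 512)
  expect_equal(s$useful, 210)
  # one hidden spike: 512 total, 5 useful
  s2 <- count_sops(branch, c(input = 0, layer1 = 1, layer2 = 0),
                   chip_morphic())
  expect_equal(s2$total, 512)
  expect_equal(s2$useful, 5)
  # zero spikes
  s0 <- count_sops(branch, c(input = 0, layer1 = 0, layer2 = 0),
                   chip_morphic())
  expect_equal(c(s0$total, s0$useful), c(0, 0))
  expect_error(count_sops(branch, c(input = 1, layer1 = 0, layer2 = 0),
                          NULL), "chip")
})

test_that("count_sops equals the brute-force per-spike oracle", {
  set.seed(11)
  for (i in 1:20) {
    fanouts <- c(sample(50:300, 1), 5L)
    spec <- network_spec("s", list(
      layer_dense(fanouts[1], neuron = neuron_config(),
                  quant = quant_spec("float")),
      layer_dense(fanouts[2], neuron = neuron_config(),
                  quant = quant_spec("float"))), input_shape = 16L)
    chip <- if (i %% 2) chip_odin() else
      chip_model("direct", 512L, 1L, 10, 1e6, crossbar = FALSE)
    tr <- c(input = sample(0:300, 1), layer1 = sample(0:300, 1),
            layer2 = sample(0:50, 1))
    got <- count_sops(spec, tr, chip)
    want <- oracle_sops(tr[1:2], fanouts, chip$neurons_per_core,
                        chip$crossbar)
    expect_identical(c(got$total, got$useful), unname(want))
  }
})

test_that("dynamic power reproduces the printed operating points", {
  # ODIN at max rate f_clk/2: 8.4 pJ * 37.5 MHz = 0.315 mW
  expect_equal(dynamic_power(chip_odin(), 75e6 / 2), 0.315)
  # MorphIC, 4 cores at max rate: 4 * 30 pJ * 27.5 MHz = 3.3 mW
  expect_equal(dynamic_power(chip_morphic(), 55e6 / 2), 3.3)
  expect_equal(dynamic_power(chip_odin(), 0), 0)
  expect_error(dynamic_power(chip_odin(), 75e6), "exceeds")
})

test_that("energy/time are consistent with dynamic power at max rate", {
  chip <- chip_morphic()
  sops <- c(2e5, 1.5e5, 1e5, 1.2e5)
  et <- energy_and_time(chip, sops)
  # busiest core at max rate: its energy/time (uJ/ms = mW) = E_SOP * f/2
  p_one_core <- chip$e_sop_pj * 1e-12 * max(sops) * 1e6 / et$time_ms
  expect_equal(p_one_core, dynamic_power(chip, chip$f_clk_hz / 2, 1))
  et0 <- energy_and_time(chip, c(0, 0, 0, 0))
  expect_equal(c(et0$energy_uJ, et0$time_ms), c(0, 0))

  # homogeneity of degree 1
  et2 <- energy_and_time(chip, 3 * sops)
  expect_equal(et2$energy_uJ, 3 * et$energy_uJ)
  expect_equal(et2$time_ms, 3 * et$time_ms)
  expect_equal(edp(3 * 7, 2), 3 * edp(7, 2))
  expect_equal(dynamic_power(chip, 2e6), 2 * dynamic_power(chip, 1e6))
})

test_that("EDP and the measured-energy identity reproduce printed values", {
  expect_equal(round(edp(7.42, 23.5), 2), 0.17)
  expect_equal(round(edp(173.2, 5.89), 1), 1.0)
  expect_equal(edp(0, 10), 0)
  # 3.3 mW x 17.3 ms = 57.09 uJ, inside the printed 57.2 +/- 6.8
  e <- dynamic_power(chip_morphic(), 55e6 / 2) * 17.3
  expect_lt(abs(e - 57.2), 6.8)
})

test_that("utilization reproduces the printed percentages", {
  expect_equal(round(utilization(spec_odin_emg(), chip_odin()), 1), 91.8)
  expect_equal(round(utilization(spec_morphic_dvs(), chip_morphic()), 1),
               42.0)
  # fusion share on MorphIC: hidden layers only (output lives on ODIN)
  expect_equal(round(utilization(NULL, chip_morphic(),
                                 n_neurons = 4 * 210), 1), 41.0)
  # fusion share on ODIN: 230 hidden + 5 fusion outputs
  expect_equal(round(utilization(NULL, chip_odin(), n_neurons = 235), 1),
               91.8)
})

test_that("fusion remapping avoids the dummy-SOP overhead", {
  expect_equal(fusion_sop_remap(1), list(total = 5, useful = 5))
  expect_equal(fusion_sop_remap(0), list(total = 0, useful = 0))
  # strictly cheaper than crossbar accounting whenever hidden spikes > 0
  for (h in c(1, 10, 500)) {
    crossbar <- count_sops(spec_morphic_branch(),
                           c(input = 0, layer1 = h, layer2 = 0),
                           chip_morphic())$total
    expect_lt(fusion_sop_remap(h)$total, crossbar)
  }
})

test_that("cost reports assemble the full chain", {
  branch <- spec_morphic_branch()
  ens <- spec_morphic_dvs()
  tr <- lapply(1:4, function(k) c(input = 1000, layer1 = 200, layer2 = 10))
  rep <- cost_report(ens, tr, chip_morphic())
  expect_equal(rep$sop_total, 4 * 1200 * 512)
  expect_equal(rep$sop_useful, 4 * (1000 * 210 + 200 * 5))
  expect_equal(rep$edp_uJs, rep$energy_uJ * rep$processing_time_ms / 1000)
  expect_gte(rep$sop_total, rep$sop_useful)
  expect_output(print(rep), "morphic")
})
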