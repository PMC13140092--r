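# shared fixture builders -- everything is generated in code at test time

CHANNELS <- c("Fz", "FCz", "Cz", "CPz", "Pz", "Oz", "Fpz", "Fp1")

# epoch set with fully specified voltages: data is trial x channel x time
h_epochs <- function(data, classes = NULL, condition = "sitting",
                     times = seq(-200, 796, 4), participant = "1") {
  ntr <- dim(data)[1]
  if (is.null(classes)) classes <- rep("frequent", ntr)
  epoch_set(times, data,
            data.frame(class = classes, condition = condition,
                       participant = participant, stringsAsFactors = FALSE),
            CHANNELS[seq_len(dim(data)[2])])
}

# constant-voltage epochs (per-trial scalar values)
h_const_epochs <- function(values, nchan = 2, ntime = 250, ...) {
  data <- array(rep(values, nchan * ntime), c(length(values), nchan, ntime))
  h_epochs(data, times = seq(-200, by = 4, length.out = ntime), ...)
}

# one ERP waveform with a single channel's values set explicitly
h_erp <- function(values, times, channel = "Pz", n_trials = 10) {
  v <- matrix(values, 1, length(times))
  erp_waveform(channel, times, v, n_trials = n_trials,
               class = "rare", condition = "sitting", participant = "1")
}

# simulate one participant's standing/sitting epoch pair and decode it
h_decode_participant <- function(p, spec, tpl, dspec, seed_base = 1,
                                 counts = c(frequent = 40)) {
  es <- baseline_correct(simulate_epochs(counts, tpl, "standing", spec, p,
                                         seed = derive_seed(seed_base, p, 1)))
  ei <- baseline_correct(simulate_epochs(counts, tpl, "sitting", spec, p,
                                         seed = derive_seed(seed_base, p, 2)))
  run_decoding(es, ei, dspec, participant = p,
               seed = derive_seed(seed_base, p, 3))
}

# cohort of decoding results (exchangeable conditions unless effect != 0)
h_decode_cohort <- function(n_participants, effect = 0, n_iterations = 10,
                            seed_base = 1, spec = NULL,
                            counts = c(frequent = 40)) {
  if (is.null(spec)) spec <- cohort_spec(p3b_effect_uV = effect)
  tpl <- default_erp_template(effect)
  dspec <- decoding_spec("frequent_only", n_iterations = n_iterations,
                         seed = seed_base)
  lapply(seq_len(n_participants), h_decode_participant,
         spec = spec, tpl = tpl, dspec = dspec, seed_base = seed_base,
         counts = counts)
}

# strongly separable decoding results: near-noise-free with a large,
# narrow condition effect centered at 400 ms
h_separable_results <- function(n_participants = 6, n_iterations = 3,
                                seed_base = 1, noise_sd = 0.3) {
  spec <- cohort_spec(noise_sd_uV = c(standing = noise_sd, sitting = noise_sd),
                      p3b_effect_uV = -5)
  tpl <- default_erp_template(-5)
  dspec <- decoding_spec("frequent_only", n_iterations = n_iterations,
                         seed = seed_base)
  lapply(seq_len(n_participants), h_decode_participant,
         spec = spec, tpl = tpl, dspec = dspec, seed_base = seed_base)
}
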