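# Heavy optimal-control solutions shared across acceptance tests.  Each is
# computed once per test run, on first use.

.acc_cache <- new.env(parent = emptyenv())

acc_amputee <- function(d_mpk = 1.0) {
  build_amputee_model(68.5, 1.78, prosthesis_spec(d_mpk = d_mpk))
}

acc_ref50 <- function() {
  if (is.null(.acc_cache$ref50)) {
    .acc_cache$ref50 <- predict_gait(acc_amputee(), prediction_problem_spec(
      target_speed = 1.48, condition = "REF", n_mesh = 50,
      solver = list(time_limit = 600)))
  }
  .acc_cache$ref50
}

# peak IL knee flexion during swing (second half of the cycle), in degrees
swing_knee_peak <- function(res) {
  sel <- res$trajectories$cycle_frac > 0.5
  max(rad2deg(res$trajectories$q[sel, "knee_il"]))
}
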