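DAY <- 86400
WEEK <- 604800

phase_d <- function(v0, v1, days) volume_phase(v0, v1, days * DAY)

traj_d <- function(..., arm = "control") {
  trajectory(list(...), arm = arm)
}

# a minimal treatment record around a treated trajectory
record_with <- function(treated, control = parse_phase_string("0.1->0.4@14d"),
                        inoculum = 1e6, dose = 840, regimen = "", id = 1L) {
  treatment_record(id, "test", "test-line", inoculum, dose, regimen,
                   control, treated)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

expect_rel <- function(x, ref, tol) expect_lt(rel_err(x, ref), tol)
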