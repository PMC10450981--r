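# Small lattices and explicit lattice-unit species used across tests.

small_geo <- function(n_sites = 30, n_lanes = 3, dt_s = 0.04)
  lattice_geometry(n_lanes = n_lanes, mt_length_nm = n_sites * 8,
                   site_spacing_nm = 8, dt_s = dt_s)

# species with lattice-unit overrides; processivity effectively unlimited
# unless stated, lifetimes long unless stated
test_species <- function(geo, v_fast = 7L, v_slow = 3L,
                         p_fast = 100000L, p_slow = 100000L,
                         lt_fast = 1000000L, lt_slow = 1000000L) {
  list(
    fast = species_params("Kin3F", 1350, 6240, 60, geo,
                          velocity_steps = v_fast,
                          processivity_sites = p_fast,
                          lifetime_iters = lt_fast),
    slow = species_params("Kin1S", 620, 1070, 60, geo,
                          velocity_steps = v_slow,
                          processivity_sites = p_slow,
                          lifetime_iters = lt_slow))
}

# run a crafted initial state with no influx for a given number of iterations
run_state <- function(scenario, initial, iters, species, seed = 1, ...) {
  run_multi(scenario, influx = influx_config(0, 0), species = species,
            horizon_s = iters * scenario$geometry$dt_s, seed = seed,
            initial = initial, ...)
}

motor_at <- function(lane, site, species = 1L)
  cbind(lane = lane, site = site, species = species)
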