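# Small in-code fixtures shared across the test files.

tiny_grid <- function(n = 16L, vs = 0.5) voxel_grid(rep(n, 3L), rep(vs, 3L))

# hand-built two-patient cohort on a tiny grid: three point-source EF
# volumes with known amplitudes and scores
toy_cohort <- function(grid = tiny_grid()) {
  recs <- data.frame(
    patient_id = c("A", "A", "B"),
    lead_id = c("A_L1", "A_L1", "B_L1"),
    tract_id = c("central", "central", "parallel"),
    depth_mm = c(-1, 3, 1),
    amplitude_mA = c(1, 1, 1),
    improvement_pct = c(100, 50, 75),
    ef_volume_ref = c("r1", "r2", "r3"),
    stringsAsFactors = FALSE
  )
  vols <- list(
    r1 = ef_point_source(c(0, 0, -1), 1, grid, record_ref = "r1"),
    r2 = ef_point_source(c(0, 0, 3), 1, grid, record_ref = "r2"),
    r3 = ef_point_source(c(1, 0, 1), 1, grid, record_ref = "r3")
  )
  new_cohort(grid, recs, vols)
}

# stack built from explicit per-voxel observations (no geometry involved)
manual_stack <- function(obs, grid = tiny_grid(4L), patients = NULL) {
  obs <- data.table::as.data.table(obs)
  if (is.null(obs$ef)) obs$ef <- 0.4
  if (is.null(obs$amplitude)) obs$amplitude <- 1
  if (is.null(obs$record)) obs$record <- paste0("r", seq_len(nrow(obs)))
  if (is.null(patients)) patients <- sort(unique(obs$patient))
  data.table::setkey(obs, voxel)
  pssmap:::finish_stack(obs, grid, threshold = 0.2, patients = patients)
}

# small cached cohorts so expensive generation runs once per test session
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

small_cfg <- function(...) {
  # coarser voxels keep the full 24 mm protocol extent at desk scale
  sim_config(n_patients = 8L, grid = voxel_grid(c(32L, 32L, 32L), 0.75),
             ...)
}

small_signal_stack <- function() {
  cached("small_signal", {
    co <- generate_cohort(small_cfg(), recovery_ground_truth(), seed = 301)
    list(cohort = co, stack = build_stack(co))
  })
}
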