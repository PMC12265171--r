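# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small unbiased phantom cohort (fast; used by several files).
tiny_cohort <- function() fixture("tiny_cohort", function() {
  make_cohort(sim_config(n_participants = 12L, seed = 7L))
})

# A toy 4x4x4 volume with distinct target/reference blocks.
toy_masks <- function() {
  tgt <- array(0, c(4, 4, 4)); tgt[1:2, , ] <- 1
  ref <- array(0, c(4, 4, 4)); ref[3:4, , ] <- 1
  mask_pair(reference = ref, target = tgt)
}

toy_transforms <- function() {
  centiloid_transforms(list(
    PIB = list(slope = 100, intercept = -100),
    FBP = list(slope = 120, intercept = -110)))
}

# Write a tiny manifest + volumes to a temp dir; returns the manifest path.
write_tiny_manifest <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  g <- volume_grid(c(4, 4, 4), 4)
  rows <- list(
    list(id = "A", date = "2020-01-01", tracer = "PIB"),
    list(id = "A", date = "2021-01-01", tracer = "PIB"),
    list(id = "A", date = "2022-01-01", tracer = "PIB"),
    list(id = "B", date = "2020-06-01", tracer = "FBP"))
  paths <- character(length(rows))
  for (i in seq_along(rows)) {
    paths[i] <- file.path(dir, sprintf("scan%d.nii.gz", i))
    save_volume(array(runif(64, 0.5, 1.5), c(4, 4, 4)), paths[i], grid = g)
  }
  df <- data.frame(participant_id = vapply(rows, `[[`, "", "id"),
                   date = vapply(rows, `[[`, "", "date"),
                   tracer = vapply(rows, `[[`, "", "tracer"),
                   psf_fwhm_mm = 5,
                   volume_path = basename(paths))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(df, mp, row.names = FALSE)
  mp
}
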