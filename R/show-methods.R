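setMethod("show", "ModelParams", function(object) {
  v <- object@values
  cat("ModelParams (", length(v), " parameters, SI units)\n", sep = "")
  cat(sprintf("  Lp %.3g m/s/Pa | A_osm %.3g m2 | eps %.3g Pa | Pc %.3g Pa\n",
              v[["Lp"]], v[["A_osm"]], v[["eps"]], v[["Pc"]]))
  cat(sprintf("  eta_eq %.3g Pa s | k1 %.3g /s | k2a %.3g m3/M/s\n",
              v[["eta_eq"]], v[["k1"]], v[["k2a"]]))
  cat(sprintf("  r0 %.3g m | Osm_i %.3g M | hash %s\n",
              v[["r0"]], v[["Osm_i"]], configHash(object)))
  invisible(object)
})

setMethod("show", "ScenarioProtocol", function(object) {
  cat(sprintf("ScenarioProtocol over [%g, %g] s\n",
              object@span[1L], object@span[2L]))
  for (nm in names(object@courses)) {
    m <- object@courses[[nm]]
    if (nrow(m) <= 2L && length(unique(m[, 2L])) == 1L) {
      cat(sprintf("  %-12s constant %.6g\n", nm, m[1L, 2L]))
    } else {
      cat(sprintf("  %-12s %d breakpoints, range [%.6g, %.6g]\n",
                  nm, nrow(m), min(m[, 2L]), max(m[, 2L])))
    }
  }
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  d <- object@data
  cat(sprintf("Trajectory: %d samples over [%g, %g] s (%d columns)\n",
              nrow(d), d$time[1L], d$time[nrow(d)], ncol(d)))
  cat(sprintf("  final: L %.4g um | P %.4g MPa | growth %.3g um/min\n",
              d$L[nrow(d)] * 1e6, d$P[nrow(d)] * 1e-6,
              d$growth_um_min[nrow(d)]))
  invisible(object)
})

setMethod("show", "OscillationSummary", function(object) {
  if (!object@oscillatory) {
    cat(sprintf("OscillationSummary '%s': non-oscillatory (baseline %.6g)\n",
                object@variable, object@baseline))
  } else {
    cat(sprintf(
      "OscillationSummary '%s': period %.4g s, amplitude %.4g, baseline %.6g\n",
      object@variable, object@period, object@amplitude, object@baseline))
    cat(sprintf("  %d cycles, %s peak pattern\n", object@n_cycles,
                object@classification))
  }
  invisible(object)
})

setMethod("show", "RegulationReport", function(object) {
  cat(sprintf("RegulationReport: %s vs %s\n", object@labels[1L],
              object@labels[2L]))
  w <- object@water; c_ <- object@wall
  cat(sprintf("  water: R_pi_i %.4g | R_pi_o %.4g | R_P %.4g (sum %.8g)\n",
              w[["R_pi_i_w"]], w[["R_pi_o_w"]], w[["R_P_w"]],
              w[["water_sum"]]))
  cat(sprintf("  wall:  R_phi %.4g | R_P %.4g | R_O %.4g (sum %.8g)\n",
              c_[["R_phi_c"]], c_[["R_P_c"]], c_[["R_O_c"]],
              c_[["wall_sum"]]))
  invisible(object)
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: objective %.6g (%s), seed %d, %d evaluations\n",
    object@objective,
    if (object@hard_ok) "hard constraints met" else "HARD CONSTRAINTS FAILED",
    as.integer(object@seed), nrow(object@log)))
  invisible(object)
})
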