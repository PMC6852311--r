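# dfgout default classifier / pipeline configuration (version 1)
#
# Angular intervals are degrees in (-180, 180]; distances are Angstrom.
# The alphaC thresholds (4.0 / 8.5 A, chi <= 100 deg) and the P-loop
# 3-of-4 rule are literature constants; the A-loop and P-loop interval
# boxes are package defaults chosen from kinase-domain anatomy (see the
# methods vignette) and are fully overridable.
version: 1
dfg:
  # pseudodihedral over (CA of DFG-1, CA of Asp184, CG of Asp184,
  # centroid of the Asp delta oxygens); interpretation documented in the
  # methods vignette
  in_interval: [40, 140]
  out_interval: [-140, -40]
alphac:
  d_in_max: 4.0
  d_out_min: 8.5
  chi_inter_max: 100.0
  chi_index: 1
ploop:
  min_conditions: 3
  classes:
    collapsed:
      psi_gmotif_m1: [-120, 40]
      psi_gmotif_p1: [-120, 40]
      xi_gmotif_p1_p2: [-180, 60]
      d_phi__hrd_p4: [8, 16]
    stretched:
      psi_gmotif_m1: [60, 180]
      psi_gmotif_p1: [60, 180]
      xi_gmotif_p1_p2: [80, 180]
      d_phi__hrd_p4: [17, 28]
aloop:
  windows:
    xi_dfg_m1_d: 182   # C-alpha window 182-185
    xi_dfg_f_g: 184    # C-alpha window 184-187
  classes:
    closed_type2:
      xi_dfg_m1_d: [-180, -60]
      xi_dfg_f_g: [-120, 0]
      d_hrd_m4__dfg_p3: [7, 14]
    open_dfg_out:
      xi_dfg_m1_d: [30, 150]
      xi_dfg_f_g: [60, 180]
      d_hrd_m4__dfg_p3: [15, 26]
    closed_a_under_p:
      xi_dfg_m1_d: [-50, 20]
      xi_dfg_f_g: [-180, -130]
      d_hrd_m4__dfg_p3: [7, 15.5]
boundaries:
  nlobe_start: 40
  nlobe_end: 120
  aloop_start: 183
  aloop_end: 208
clash:
  cutoff: 2.5
alignment:
  gap_open: 10
  gap_extend: 0.5
  score_floor: 150
match:
  rmsd_threshold: 0.7
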