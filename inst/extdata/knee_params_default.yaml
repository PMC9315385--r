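# Default planar knee model parameters (semantic version below).
#
# The model is a stylized sagittal-plane knee: one revolute joint, seven
# muscles, rigid tendons.  Knee angle is measured in degrees of flexion
# (0 = fully extended).  Moment arms are signed in the anatomical sense:
# positive = extensor, negative = flexor.  TA acts about the ankle and is
# carried only for interface parity with the 7-channel recordings, so its
# knee moment arm is zero.
#
# Values are literature-plausible approximations for a ~75 kg adult, not a
# digitized anatomy.  Analyses built on this model should compare against
# oracles computed from these same parameters, not against absolute
# anatomical references.
version: "1.0.0"
limb:
  mass_kg: 4.6            # shank + foot
  inertia_kgm2: 0.40      # about the knee axis
  com_m: 0.26             # knee-to-centre-of-mass distance
  gravity_ms2: 0.0        # supine, fully supported limb
  damping_nms_per_rad: 1.5
  range_deg: [0.0, 120.0]
  stop_stiffness_nm_per_deg: 50.0
muscles:
  RF:
    fmax_n: 1169.0
    l0_m: 0.076
    fl_width: 0.45
    kpe: 4.0
    e0_strain: 0.6
    vmax_l0_per_s: 10.0
    fv_shape: 0.25
    fv_ecc_max: 1.4
    fv_ecc_shape: 0.08
    moment_arm_poly_m: [0.038, 1.2e-4]
    fiberlen_affine: [0.58, 4.2e-3]
  VL:
    fmax_n: 1871.0
    l0_m: 0.084
    fl_width: 0.45
    kpe: 4.0
    e0_strain: 0.6
    vmax_l0_per_s: 10.0
    fv_shape: 0.25
    fv_ecc_max: 1.4
    fv_ecc_shape: 0.08
    moment_arm_poly_m: [0.038, 1.2e-4]
    fiberlen_affine: [0.58, 4.2e-3]
  VM:
    fmax_n: 1294.0
    l0_m: 0.089
    fl_width: 0.45
    kpe: 4.0
    e0_strain: 0.6
    vmax_l0_per_s: 10.0
    fv_shape: 0.25
    fv_ecc_max: 1.4
    fv_ecc_shape: 0.08
    moment_arm_poly_m: [0.038, 1.2e-4]
    fiberlen_affine: [0.58, 4.2e-3]
  Se:
    fmax_n: 410.0
    l0_m: 0.16
    fl_width: 0.45
    kpe: 4.0
    e0_strain: 0.6
    vmax_l0_per_s: 10.0
    fv_shape: 0.25
    fv_ecc_max: 1.4
    fv_ecc_shape: 0.08
    moment_arm_poly_m: [-0.036, 8.0e-5]
    fiberlen_affine: [1.05, -2.5e-3]
  BF:
    fmax_n: 896.0
    l0_m: 0.11
    fl_width: 0.45
    kpe: 4.0
    e0_strain: 0.6
    vmax_l0_per_s: 10.0
    fv_shape: 0.25
    fv_ecc_max: 1.4
    fv_ecc_shape: 0.08
    moment_arm_poly_m: [-0.032, 7.0e-5]
    fiberlen_affine: [1.05, -2.5e-3]
  MG:
    fmax_n: 1558.0
    l0_m: 0.06
    fl_width: 0.45
    kpe: 4.0
    e0_strain: 0.6
    vmax_l0_per_s: 10.0
    fv_shape: 0.25
    fv_ecc_max: 1.4
    fv_ecc_shape: 0.08
    moment_arm_poly_m: [-0.020, 5.0e-5]
    fiberlen_affine: [1.05, -2.5e-3]
  TA:
    fmax_n: 905.0
    l0_m: 0.098
    fl_width: 0.45
    kpe: 4.0
    e0_strain: 0.6
    vmax_l0_per_s: 10.0
    fv_shape: 0.25
    fv_ecc_max: 1.4
    fv_ecc_shape: 0.08
    moment_arm_poly_m: [0.0]
    fiberlen_affine: [1.0, 0.0]
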