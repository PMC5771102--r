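{
  "params": {
    "L1": 20,
    "L2": 80,
    "D0": 10,
    "D1": 7.937005259841,
    "phi": 60,
    "Dt": 120,
    "Lt": 100,
    "bend_radius": 40,
    "phi_ref": "axis",
    "alpha": 1.0471975511966
  },
  "probes": [
    {
      "Dp": 4,
      "Lp": 22,
      "Ld": 30,
      "axis": [0, 1, 0],
      "tip_center": null
    }
  ],
  "h": 2,
  "V": 0.2,
  "flow": "analytic",
  "dt_scale": 10,
  "end_time": 1200,
  "metric_interval": 1,
  "checkpoint_times": [],
  "props": {
    "Ct": 3.6,
    "Cf": 1.8,
    "Cb": 3.6,
    "Qf": 250,
    "kappa_f": 2,
    "kappa_t": 0.5,
    "kappa_b": 0.5,
    "omega_cb": 0.0005,
    "Qm": 420,
    "Tu": -1,
    "Tl": -8,
    "Tcb": 37
  },
  "bounds": {
    "T_inlet": 37,
    "T_probe": -196,
    "shell": "adiabatic",
    "outlet": "zero-gradient"
  },
  "advection_order": 1,
  "sample_point": null,
  "max_overlap": 1.5,
  "fine_until": 0,
  "stop_when_wall_frozen": false
}
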