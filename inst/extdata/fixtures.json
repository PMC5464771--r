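{
  "tracks": {
    "icam-0.5kPa": {
      "speed_mean_um_min": 12.4,
      "speed_sd_um_min": 3.0,
      "frac_arrested": 0.0,
      "persistence": 0.7,
      "dt_s": 5,
      "duration_s": 300,
      "source": "speed mean 12.4 +/- 0.3 um/min (SEM) printed for ICAM-1-coated 0.5 kPa gels; SD synthetic, chosen to reproduce the printed SEM at n = 100"
    },
    "icam-6.4kPa": {
      "speed_mean_um_min": 13.1,
      "speed_sd_um_min": 3.0,
      "frac_arrested": 0.0,
      "persistence": 0.7,
      "dt_s": 5,
      "duration_s": 300,
      "source": "speed mean 13.1 +/- 0.3 um/min (SEM) printed for ICAM-1-coated 6.4 kPa gels; SD synthetic"
    },
    "icam-100kPa": {
      "speed_mean_um_min": 15.5,
      "speed_sd_um_min": 4.0,
      "frac_arrested": 0.0,
      "persistence": 0.7,
      "dt_s": 5,
      "duration_s": 300,
      "source": "speed mean 15.5 +/- 0.4 um/min (SEM) printed for ICAM-1-coated 100 kPa gels; SD synthetic, chosen so the cohort SEM is about 0.4 at n = 100"
    },
    "acd3-0.5kPa": {
      "speed_mean_um_min": 12.0,
      "speed_sd_um_min": 3.0,
      "frac_arrested": 0.3,
      "persistence": 0.7,
      "dt_s": 5,
      "duration_s": 300,
      "source": "synthetic: arrest fraction figure-encoded, only the soft < mid < stiff < glass ordering is preserved"
    },
    "acd3-6.4kPa": {
      "speed_mean_um_min": 12.0,
      "speed_sd_um_min": 3.0,
      "frac_arrested": 0.45,
      "persistence": 0.7,
      "dt_s": 5,
      "duration_s": 300,
      "source": "synthetic: arrest fraction figure-encoded, ordering only"
    },
    "acd3-100kPa": {
      "speed_mean_um_min": 12.0,
      "speed_sd_um_min": 3.0,
      "frac_arrested": 0.6,
      "persistence": 0.7,
      "dt_s": 5,
      "duration_s": 300,
      "source": "synthetic: arrest fraction figure-encoded, ordering only"
    },
    "acd3-glass": {
      "speed_mean_um_min": 12.0,
      "speed_sd_um_min": 3.0,
      "frac_arrested": 0.75,
      "persistence": 0.7,
      "dt_s": 5,
      "duration_s": 300,
      "source": "synthetic: arrest fraction figure-encoded, ordering only"
    }
  },
  "indentation": {
    "hela-1.5kPa": {
      "E_true_pa": 1430,
      "R_um": 5.7,
      "k_nN_um": 3.0,
      "nu_cell": 0.5,
      "delta_max_um": 2.0,
      "n_points": 50,
      "force_noise_cv": 0.03,
      "source": "Young's modulus 1.43 +/- 0.15 kPa printed for HeLa-CIITA cells on 1.5 kPa PDMS; probe constants printed (R = 5.7 um, k = 3 nN/um, nu = 0.5); noise level synthetic"
    },
    "hela-28kPa": {
      "E_true_pa": 1720,
      "R_um": 5.7,
      "k_nN_um": 3.0,
      "nu_cell": 0.5,
      "delta_max_um": 2.0,
      "n_points": 50,
      "force_noise_cv": 0.03,
      "source": "Young's modulus 1.72 +/- 0.2 kPa printed for HeLa-CIITA cells on 28 kPa PDMS; noise level synthetic"
    }
  },
  "gels": {
    "pa-0.5kPa": {
      "acrylamide_pct": 3,
      "bis_pct": 0.25,
      "E_pa": 513,
      "E_sem_pa": 48,
      "E_source": "measured (gap-sweep plateau, converted with nu = 0.45)",
      "G_plateau_pa": 176.9,
      "G_source": "back-computed from the printed E as E / 2.9; the sweep-level G' is not printed for this formulation"
    },
    "pa-6.4kPa": {
      "acrylamide_pct": 5,
      "bis_pct": 0.5,
      "E_pa": 6416,
      "E_sem_pa": 228,
      "E_source": "measured (gap-sweep plateau, converted with nu = 0.45)",
      "G_plateau_pa": 2212,
      "G_sem_pa": 79,
      "G_source": "printed mean over n = 15 samples"
    },
    "pa-100kPa": {
      "acrylamide_pct": 18,
      "bis_pct": 0.38,
      "E_pa": 100000,
      "E_source": "reported (literature value cited, not measured by gap sweep here)",
      "G_plateau_pa": null,
      "G_source": "not available"
    }
  }
}
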