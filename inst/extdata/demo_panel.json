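{
  "version": "1.0",
  "ph_range": [6.4, 7.6],
  "temp_levels_K": [300, 302.7],
  "components": [
    {
      "name": "citrate",
      "role": "active_metabolite",
      "conc_range": [500, 6000],
      "nmr_visible": true,
      "spin_systems": ["cit_h1", "cit_h2"]
    },
    {
      "name": "creatinine",
      "role": "active_metabolite",
      "conc_range": [2400, 24000],
      "nmr_visible": true,
      "spin_systems": ["cre_h3", "cre_h7"]
    },
    {
      "name": "glycine",
      "role": "active_metabolite",
      "conc_range": [300, 4000],
      "nmr_visible": true,
      "spin_systems": "gly_h2"
    },
    {
      "name": "histidine",
      "role": "active_metabolite",
      "conc_range": [100, 1300],
      "nmr_visible": true,
      "spin_systems": "his_h5"
    },
    {
      "name": "3-methylhistidine",
      "role": "active_metabolite",
      "conc_range": [50, 600],
      "nmr_visible": true,
      "spin_systems": "mhis_h5"
    },
    {
      "name": "TMAO",
      "role": "active_metabolite",
      "conc_range": [200, 1500],
      "nmr_visible": true,
      "spin_systems": "tmao_h1"
    },
    {
      "name": "hippurate",
      "role": "active_metabolite",
      "conc_range": [200, 3500],
      "nmr_visible": true,
      "spin_systems": "hip_h7"
    },
    {
      "name": "alanine",
      "role": "active_metabolite",
      "conc_range": [100, 700],
      "nmr_visible": true,
      "spin_systems": "ala_h3"
    },
    {
      "name": "lactate",
      "role": "active_metabolite",
      "conc_range": [100, 1200],
      "nmr_visible": true,
      "spin_systems": "lac_h3"
    },
    {
      "name": "succinate",
      "role": "active_metabolite",
      "conc_range": [20, 300],
      "nmr_visible": true,
      "spin_systems": "suc_h2"
    },
    {
      "name": "taurine",
      "role": "active_metabolite",
      "conc_range": [200, 1600],
      "nmr_visible": true,
      "spin_systems": "tau_h1"
    },
    {
      "name": "formate",
      "role": "active_metabolite",
      "conc_range": [100, 600],
      "nmr_visible": true,
      "spin_systems": "for_h1"
    },
    {
      "name": "creatine",
      "role": "passive_metabolite",
      "conc_range": [50, 400],
      "nmr_visible": true,
      "spin_systems": "crt_h2"
    },
    {
      "name": "dimethylamine",
      "role": "passive_metabolite",
      "conc_range": [100, 600],
      "nmr_visible": true,
      "spin_systems": "dma_h1"
    },
    {
      "name": "Na+",
      "role": "inorganic_ion",
      "conc_range": [40000, 220000],
      "nmr_visible": false,
      "spin_systems": []
    },
    {
      "name": "Cl-",
      "role": "inorganic_ion",
      "conc_range": [40000, 240000],
      "nmr_visible": false,
      "spin_systems": []
    },
    {
      "name": "K+",
      "role": "inorganic_ion",
      "conc_range": [25000, 125000],
      "nmr_visible": false,
      "spin_systems": []
    },
    {
      "name": "Ca2+",
      "role": "inorganic_ion",
      "conc_range": [1000, 10000],
      "nmr_visible": false,
      "spin_systems": []
    },
    {
      "name": "Mg2+",
      "role": "inorganic_ion",
      "conc_range": [1000, 8000],
      "nmr_visible": false,
      "spin_systems": []
    },
    {
      "name": "phosphate",
      "role": "inorganic_ion",
      "conc_range": [10000, 50000],
      "nmr_visible": false,
      "spin_systems": []
    },
    {
      "name": "sulfate",
      "role": "inorganic_ion",
      "conc_range": [5000, 25000],
      "nmr_visible": false,
      "spin_systems": []
    },
    {
      "name": "albumin",
      "role": "protein",
      "conc_range": [0.2, 3],
      "nmr_visible": false,
      "spin_systems": []
    }
  ],
  "spin_systems": [
    {
      "id": "cit_h1",
      "metabolite": "citrate",
      "proton_label": "H3,6a",
      "multiplicity": "dd",
      "n_protons": 2,
      "j_hz": 15.9,
      "delta_free": 2.54,
      "window": [2.49, 2.6],
      "is_navigator": true
    },
    {
      "id": "cit_h2",
      "metabolite": "citrate",
      "proton_label": "H3,6b",
      "multiplicity": "dd",
      "n_protons": 2,
      "j_hz": 15.9,
      "delta_free": 2.66,
      "window": [2.61, 2.71],
      "is_navigator": true
    },
    {
      "id": "cre_h3",
      "metabolite": "creatinine",
      "proton_label": "H3",
      "multiplicity": "s",
      "n_protons": 3,
      "j_hz": [],
      "delta_free": 3.045,
      "window": [3, 3.09],
      "is_navigator": true
    },
    {
      "id": "cre_h7",
      "metabolite": "creatinine",
      "proton_label": "H7",
      "multiplicity": "s",
      "n_protons": 2,
      "j_hz": [],
      "delta_free": 4.06,
      "window": [4.01, 4.11],
      "is_navigator": true
    },
    {
      "id": "gly_h2",
      "metabolite": "glycine",
      "proton_label": "H2",
      "multiplicity": "s",
      "n_protons": 2,
      "j_hz": [],
      "delta_free": 3.56,
      "window": [3.5, 3.62],
      "is_navigator": true
    },
    {
      "id": "his_h5",
      "metabolite": "histidine",
      "proton_label": "H5",
      "multiplicity": "s",
      "n_protons": 1,
      "j_hz": [],
      "delta_free": 7.8,
      "window": [7.68, 7.98],
      "is_navigator": false
    },
    {
      "id": "mhis_h5",
      "metabolite": "3-methylhistidine",
      "proton_label": "H5",
      "multiplicity": "s",
      "n_protons": 1,
      "j_hz": [],
      "delta_free": 7.62,
      "window": [7.54, 7.67],
      "is_navigator": false
    },
    {
      "id": "tmao_h1",
      "metabolite": "TMAO",
      "proton_label": "H1",
      "multiplicity": "s",
      "n_protons": 9,
      "j_hz": [],
      "delta_free": 3.27,
      "window": [3.22, 3.32],
      "is_navigator": false
    },
    {
      "id": "hip_h7",
      "metabolite": "hippurate",
      "proton_label": "H7",
      "multiplicity": "d",
      "n_protons": 2,
      "j_hz": 5.9,
      "delta_free": 3.97,
      "window": [3.935, 4],
      "is_navigator": false
    },
    {
      "id": "ala_h3",
      "metabolite": "alanine",
      "proton_label": "H3",
      "multiplicity": "d",
      "n_protons": 3,
      "j_hz": 7.26,
      "delta_free": 1.48,
      "window": [1.44, 1.52],
      "is_navigator": false
    },
    {
      "id": "lac_h3",
      "metabolite": "lactate",
      "proton_label": "H3",
      "multiplicity": "d",
      "n_protons": 3,
      "j_hz": 6.94,
      "delta_free": 1.33,
      "window": [1.29, 1.37],
      "is_navigator": false
    },
    {
      "id": "suc_h2",
      "metabolite": "succinate",
      "proton_label": "H2,3",
      "multiplicity": "s",
      "n_protons": 4,
      "j_hz": [],
      "delta_free": 2.41,
      "window": [2.37, 2.45],
      "is_navigator": false
    },
    {
      "id": "tau_h1",
      "metabolite": "taurine",
      "proton_label": "H1",
      "multiplicity": "t",
      "n_protons": 2,
      "j_hz": 6.6,
      "delta_free": 3.42,
      "window": [3.37, 3.47],
      "is_navigator": false
    },
    {
      "id": "for_h1",
      "metabolite": "formate",
      "proton_label": "H1",
      "multiplicity": "s",
      "n_protons": 1,
      "j_hz": [],
      "delta_free": 8.45,
      "window": [8.4, 8.5],
      "is_navigator": false
    },
    {
      "id": "crt_h2",
      "metabolite": "creatine",
      "proton_label": "H2",
      "multiplicity": "s",
      "n_protons": 2,
      "j_hz": [],
      "delta_free": 3.93,
      "window": [3.9, 3.955],
      "is_navigator": false
    },
    {
      "id": "dma_h1",
      "metabolite": "dimethylamine",
      "proton_label": "H1",
      "multiplicity": "s",
      "n_protons": 6,
      "j_hz": [],
      "delta_free": 2.76,
      "window": [2.73, 2.79],
      "is_navigator": false
    }
  ]
}
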