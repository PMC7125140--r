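{
  "schema": 1,
  "note": "Built-in minimal Clb/Cdk1 cell-cycle network designs (synthetic reconstructions; see the methods vignette).",
  "observables": {"Sic1": "s", "Clb5": "x", "Clb3": "y", "Clb2": "z"},
  "peak_order": ["Sic1", "Clb5", "Clb3", "Clb2"],
  "designs": {
    "1A": {"file": "design1A.gma", "k_param": null, "family": "mass_action"},
    "1B": {"file": "design1B.gma", "k_param": null, "family": "mass_action"},
    "1C": {"file": "design1C.gma", "k_param": null, "family": "mass_action"},
    "2":  {"file": "design2.gma",  "k_param": null, "family": "mass_action"},
    "3":  {"file": "design3.gma",  "k_param": null, "family": "qssa"},
    "4":  {"file": "design4.gma",  "k_param": "K_zx", "family": "qssa"},
    "5":  {"file": "design5.gma",  "k_param": "K_zs", "family": "qssa"},
    "6":  {"file": "design6.gma",  "k_param": "K_cs", "family": "qssa"},
    "7":  {"file": "design7.gma",  "k_param": "K_s",  "family": "qssa"},
    "8":  {"file": "design8.gma",  "k_param": "K_s",  "family": "qssa"},
    "9":  {"file": "design9.gma",  "k_param": "K_ss", "family": "qssa"}
  }
}
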