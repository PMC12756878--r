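protocol_id: RP1
reference_state: 5S
steps:
  - {label: ce1,    titrant: none,             target_concentration: "",          pathway_state: ce,          coupling_state: R,   substrate_annotation: "",      multi_titration: false, role: state}
  - {label: "+Dig", titrant: digitonin,        target_concentration: "10 ug/mL",  pathway_state: ren,         coupling_state: ren, substrate_annotation: "",      multi_titration: false, role: preparatory}
  - {label: 1PM,    titrant: pyruvate+malate,  target_concentration: "5 mM + 2 mM", pathway_state: "N{PM}_L", coupling_state: L,   substrate_annotation: "{PM}",  multi_titration: false, role: state}
  - {label: 2D,     titrant: ADP,              target_concentration: "2.5 mM",    pathway_state: "N{PM}_P",   coupling_state: P,   substrate_annotation: "{PM}",  multi_titration: false, role: state}
  - {label: 2c,     titrant: cytochrome c,     target_concentration: "10 uM",     pathway_state: "N{PM}[c]_P", coupling_state: P,  substrate_annotation: "[c]",   multi_titration: false, role: state}
  - {label: 3U,     titrant: CCCP,             target_concentration: optimum,     pathway_state: "N{PM}_E",   coupling_state: E,   substrate_annotation: "{PM}",  multi_titration: true,  role: state}
  - {label: 4G,     titrant: glutamate,        target_concentration: "10 mM",     pathway_state: N_E,         coupling_state: E,   substrate_annotation: "{PGM}", multi_titration: false, role: state}
  - {label: 5S,     titrant: succinate,        target_concentration: "10 mM",     pathway_state: NS_E,        coupling_state: E,   substrate_annotation: "",      multi_titration: false, role: state}
  - {label: 6Oct,   titrant: octanoylcarnitine, target_concentration: "0.5 mM",   pathway_state: FNS_E,       coupling_state: E,   substrate_annotation: "",      multi_titration: false, role: state}
  - {label: 7Rot,   titrant: rotenone,         target_concentration: "0.5 uM",    pathway_state: S_E,         coupling_state: E,   substrate_annotation: "",      multi_titration: false, role: state}
  - {label: 8Gp,    titrant: glycerophosphate, target_concentration: "10 mM",     pathway_state: SGp_E,       coupling_state: E,   substrate_annotation: "",      multi_titration: false, role: state}
  - {label: 9Ama,   titrant: antimycin A,      target_concentration: "2.5 uM",    pathway_state: rox,         coupling_state: rox, substrate_annotation: "",      multi_titration: false, role: state}
  - {label: 10AsTm, titrant: ascorbate+TMPD,   target_concentration: "2 mM + 0.5 mM", pathway_state: CIV_E,   coupling_state: CIV, substrate_annotation: "",      multi_titration: false, role: state}
  - {label: 11Azd,  titrant: azide,            target_concentration: "200 mM",    pathway_state: chb,         coupling_state: chb, substrate_annotation: "",      multi_titration: false, role: state}
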