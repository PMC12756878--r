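protocol_id: RP2
reference_state: 7U
steps:
  - {label: ce1,    titrant: none,             target_concentration: "",          pathway_state: ce,          coupling_state: R,   substrate_annotation: "",     multi_titration: false, role: state}
  - {label: "+Dig", titrant: digitonin,        target_concentration: "10 ug/mL",  pathway_state: ren,         coupling_state: ren, substrate_annotation: "",     multi_titration: false, role: preparatory}
  - {label: "+D",   titrant: ADP,              target_concentration: "2.5 mM",    pathway_state: ren,         coupling_state: ren, substrate_annotation: "",     multi_titration: false, role: preparatory}
  - {label: "+M.1", titrant: malate,           target_concentration: "0.1 mM",    pathway_state: "(M.1)_P",   coupling_state: P,   substrate_annotation: "",     multi_titration: false, role: preparatory}
  - {label: 1Oct,   titrant: octanoylcarnitine, target_concentration: "0.5 mM",   pathway_state: F_P,         coupling_state: P,   substrate_annotation: "",     multi_titration: false, role: state}
  - {label: 1c,     titrant: cytochrome c,     target_concentration: "10 uM",     pathway_state: "F[c]_P",    coupling_state: P,   substrate_annotation: "[c]",  multi_titration: false, role: state}
  - {label: 2M2,    titrant: malate,           target_concentration: "2 mM",      pathway_state: "F(N)_P",    coupling_state: P,   substrate_annotation: "",     multi_titration: false, role: state}
  - {label: 3P,     titrant: pyruvate,         target_concentration: "5 mM",      pathway_state: "FN{PM}_P",  coupling_state: P,   substrate_annotation: "{PM}", multi_titration: false, role: state}
  - {label: 4G,     titrant: glutamate,        target_concentration: "10 mM",     pathway_state: FN_P,        coupling_state: P,   substrate_annotation: "{PGM}", multi_titration: false, role: state}
  - {label: 5S,     titrant: succinate,        target_concentration: "10 mM",     pathway_state: FNS_P,       coupling_state: P,   substrate_annotation: "",     multi_titration: false, role: state}
  - {label: 6Gp,    titrant: glycerophosphate, target_concentration: "10 mM",     pathway_state: FNSGp_P,     coupling_state: P,   substrate_annotation: "",     multi_titration: false, role: state}
  - {label: 7U,     titrant: CCCP,             target_concentration: optimum,     pathway_state: FNSGp_E,     coupling_state: E,   substrate_annotation: "",     multi_titration: true,  role: state}
  - {label: 8Rot,   titrant: rotenone,         target_concentration: "0.5 uM",    pathway_state: SGp_E,       coupling_state: E,   substrate_annotation: "",     multi_titration: false, role: state}
  - {label: 9Ama,   titrant: antimycin A,      target_concentration: "2.5 uM",    pathway_state: rox,         coupling_state: rox, substrate_annotation: "",     multi_titration: false, role: state}
  - {label: 10AsTm, titrant: ascorbate+TMPD,   target_concentration: "2 mM + 0.5 mM", pathway_state: CIV_E,   coupling_state: CIV, substrate_annotation: "",     multi_titration: false, role: state}
  - {label: 11Azd,  titrant: azide,            target_concentration: "200 mM",    pathway_state: chb,         coupling_state: chb, substrate_annotation: "",     multi_titration: false, role: state}
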