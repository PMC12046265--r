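{
  "qualities": ["dull", "heavy", "tight", "pressure", "sharp", "burning"],
  "associated": [
    "shortness_of_breath", "palpitations", "racing_heart",
    "lightheaded", "faint", "dizzy"
  ],
  "regions": [
    {"code": "chest_center", "side": "front", "label": "Center of chest"},
    {"code": "chest_left", "side": "front", "label": "Left chest"},
    {"code": "chest_right", "side": "front", "label": "Right chest"},
    {"code": "jaw_left", "side": "front", "label": "Left jaw"},
    {"code": "jaw_right", "side": "front", "label": "Right jaw"},
    {"code": "neck", "side": "front", "label": "Neck / throat"},
    {"code": "shoulder_left", "side": "front", "label": "Left shoulder"},
    {"code": "shoulder_right", "side": "front", "label": "Right shoulder"},
    {"code": "arm_left", "side": "front", "label": "Left arm"},
    {"code": "arm_right", "side": "front", "label": "Right arm"},
    {"code": "axilla_left", "side": "front", "label": "Left axilla (armpit)"},
    {"code": "axilla_right", "side": "front", "label": "Right axilla (armpit)"},
    {"code": "abdomen_upper", "side": "front", "label": "Upper abdomen"},
    {"code": "back_upper", "side": "back", "label": "Upper back"},
    {"code": "back_mid", "side": "back", "label": "Mid back (between shoulder blades)"},
    {"code": "back_lower", "side": "back", "label": "Lower back"},
    {"code": "shoulder_blade_left", "side": "back", "label": "Left shoulder blade"},
    {"code": "shoulder_blade_right", "side": "back", "label": "Right shoulder blade"}
  ]
}
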