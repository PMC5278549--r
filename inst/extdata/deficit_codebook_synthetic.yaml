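- name: synthetic_deficit_01
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_02
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_03
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_04
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_05
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_06
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_07
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_08
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_09
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_10
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_11
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_12
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_13
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_14
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_15
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_16
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_17
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_18
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_19
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_20
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_21
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_22
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_23
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_24
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_25
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_26
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_27
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_28
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_29
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_30
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_31
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_32
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_33
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_34
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_35
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_deficit_36
  kind: dichotomous
  levels:
    'no': 0.0
    'yes': 1.0
- name: synthetic_graded_37
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
- name: synthetic_graded_38
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
- name: synthetic_graded_39
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
- name: synthetic_graded_40
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
- name: synthetic_graded_41
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
- name: synthetic_graded_42
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
- name: synthetic_graded_43
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
- name: synthetic_graded_44
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
- name: synthetic_graded_45
  kind: polychotomous
  levels:
  - none
  - mild
  - moderate
  - severe
  - disabling
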