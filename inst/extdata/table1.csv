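participant,steps_backward,foot_off_backward_ms,nonsteps_backward,steps_forward,foot_off_forward_ms,nonsteps_forward
S01,25,411.7,17,20,572.5,15
S02,31,598.5,23,31,632.5,22
S03,35,600.9,24,24,745.9,35
S04,41,318.2,18,31,387.8,27
S05,43,472.2,36,36,688.7,36
S06,51,448.5,22,35,607.7,38
S07,40,443.6,16,31,468.6,25
S08,45,306.3,9,27,386.7,31
S09,33,371.1,30,27,540.6,36
S10,41,499.2,37,45,450.4,31
S11,57,287.2,21,54,397.9,19
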