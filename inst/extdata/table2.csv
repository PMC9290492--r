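participant,n1_step_backward_ms,n1_nonstep_backward_ms,n1_step_forward_ms,n1_nonstep_forward_ms
S01,179.0,195.4,176.4,190.4
S02,189.9,206.2,193.2,203.8
S03,167.9,187.9,176.3,184.4
S04,174.1,183.5,175.7,182.0
S05,177.3,192.1,180.6,187.2
S06,168.4,177.9,170.0,175.1
S07,178.0,196.4,177.9,196.4
S08,176.4,190.3,173.3,188.7
S09,168.4,185.0,167.1,177.4
S10,175.8,188.7,173.2,193.4
S11,170.2,191.4,173.8,195.2
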