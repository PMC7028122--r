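# synthetic participant table (tabvis fixture)
participant_id,faces_run1,faces_run2,search_run1,search_run2,acuity_logmar,contrast_logcs,digit_span,usability_faces,usability_search
P001,2.92433381451604,2.67449160831120,1.74320941422745,1.89572624108118,-0.11,1.87,19,9.7,8.9
P002,2.83701595351527,3.35424397410910,2.10579472779682,1.65516531007515,-0.03,1.88,18,9.8,9.9
P003,2.91929136913344,2.75063859235704,1.83438648813779,1.57506155384971,0.06,1.84,20,9.8,10.0
P004,3.24602367844725,3.83002727499697,1.52090191965224,1.86315145380395,-0.09,1.71,18,9.6,9.8
P005,2.76212714553533,3.01557858131402,2.19167217669029,1.47646454119957,-0.01,1.83,32,9.5,9.9
P006,3.36587049628074,3.73005403481073,1.58115172950740,1.49028214637297,-0.07,1.80,25,10.0,9.8
P007,NA,NA,3.05176348830045,1.65890873400479,0.18,1.75,25,9.7,9.6
P008,NA,NA,1.51216321054129,1.34288064766455,-0.06,2.00,17,10.0,9.9
P009,NA,NA,1.10787590068340,1.58075637440808,-0.08,1.84,23,9.9,10.0
P010,NA,NA,1.02405400036921,1.48521780112877,-0.15,1.89,23,9.7,9.9
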