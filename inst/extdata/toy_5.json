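{"name":"toy-5","age":45,"segments":{"id":[1,2,3,4,5],"name":["Root","Carotid-like","Systemic branch","Cerebral A","Cerebral B"],"d_base_mm":[12,6,7,4,4],"length_mm":[60,50,50,40,40],"is_aortic":[false,false,false,false,false],"is_cow":[true,true,true,true,true],"eh_override":[null,null,null,null,null],"d_lo":[8,3,4,2,2],"d_hi":[16,9,10,6,6],"l_lo":[36,30,30,24,24],"l_hi":[84,70,70,56,56],"diameter_mm":[12,6,7,4,4],"Eh":[519.01615803109928,266.46233389731799,305.38310939690132,217.17016848650334,217.17016848650334],"A0_mm2":[113.09733552923255,28.274333882308138,38.484510006474963,12.566370614359172,12.566370614359172],"n_nodes":[13,11,11,9,9],"P0_mmHg":[85,85,85,85,85],"sigma":[0.5,0.5,0.5,0.5,0.5]},"junctions":[{"segments":[1,2,3],"ends":["end","start","start"]},{"segments":[2,4,5],"ends":["end","start","start"]}],"outlets":{"segment_id":[3,4,5],"R1":[0.80000000000000004,1.6000000000000001,1.6000000000000001],"R2":[3.2000000000000002,6.4000000000000004,6.4000000000000004],"C":[0.5,0.14999999999999999,0.14999999999999999],"PR_base":[4,8,8],"is_cow_outlet":[false,true,true],"body_block":[1,1,1],"pr_lo":[null,2,2],"pr_hi":[null,30,30]},"body_blocks":{"name":["body"],"R":[0.080000000000000002],"L":[0.00050000000000000001],"C":[40],"P_init":[9]},"heart":{"root_segment_id":1,"Emax":2.5,"Emin":0.080000000000000002,"V0":10,"Tvc":0.29999999999999999,"Tvr":0.14999999999999999,"Tc":1,"R_av":0.02,"R_mv":0.01,"C_at":15,"P_at0":8,"V_lv0":130},"stenoses":{},"cow_inlet_ids":2,"cow_outlet_ids":[4,5],"cow_segment_ids":[1,2,3,4,5],"map_segment_id":1,"eh_law":{"k1":20000000,"k2":-22.530000000000001,"k3":865000},"age_table":{"reference_age":45,"age":[25,45,65,90],"d_scale":[0.95999999999999996,1,1.05,1.1000000000000001],"eh_scale":[0.80000000000000004,1,1.55,2.3999999999999999]},"pr_split":0.20000000000000001,"stenosis_hosts":{"host_segment_id":[2],"side":["L"],"dn_lo":[2.8999999999999999],"dn_hi":[7]},"target_dx_mm":5}
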