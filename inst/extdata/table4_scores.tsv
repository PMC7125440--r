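patient_id	registry	omop
f9b6a782-bbf5-4be8-bf7e-d1a9586d9552	39	28
c2e2e081-4c39-4201-8a27-7b469ed39490	41	34
db2d85aa-4f94-4e77-8755-6b94a710c1aa	42	32
2fbc25da-3965-49c4-866f-72cf0abc2417	48	30
940171e7-d358-463a-8d9a-2b2fa90c2a84	31	41
f0314175-2d19-4146-8754-fc5aed3ab420	29	39
c7dbcfac-37ea-43f8-8899-1a9f2fb56341	15	33
ef5c3164-6f45-4d3a-88f0-4509226c5571	50	29
ec3d977b-c310-4df3-a444-f79bc3dd8b58	35	33
131cf62d-ad78-49c1-a699-5bcc1004cd12	35	33
cf11c31c-f4c3-48ba-9c46-66f406d0b7a1	47	29
ccc2ba97-912f-4b62-b767-cca129ee6a56	13	33
104ec531-5d95-41e2-ac72-f6cff2006b8e	35	24
a5627ac3-450d-4036-ade8-99ae62a5c232	45	34
5189efbe-3382-4353-ad2f-9afd0255c2c8	47	38
253f0e2d-bebd-464b-81c5-8dd8385192b3	46	37
d199cfb0-91e8-471d-b1b3-53189cd64ee0	44	33
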