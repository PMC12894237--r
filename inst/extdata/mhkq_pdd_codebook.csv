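item_id,wording,community,response_type,key
MHKQ1,Psychological health is part of overall health,knowledge,yes_no,positive
MHKQ2,Mental illness is merely a problem of thought or ideology,knowledge,yes_no,positive
MHKQ3,Many people have mental health problems without being aware of them,knowledge,yes_no,positive
MHKQ4,Mental illnesses are caused solely by psychological trauma,knowledge,yes_no,positive
MHKQ5,Mental health includes normal intelligence and stable emotions and good adaptability,knowledge,yes_no,positive
MHKQ6,Most mental illnesses are incurable,knowledge,yes_no,positive
MHKQ7,Suspected mental health problems warrant help from a psychotherapist or psychiatrist,knowledge,yes_no,positive
MHKQ8,People of almost any age can experience mental health problems,knowledge,yes_no,positive
MHKQ9,Mental illnesses and psychological problems cannot be prevented,knowledge,yes_no,positive
MHKQ10,Short-term medication suffices for severe mental illness without long-term adherence,knowledge,yes_no,positive
MHKQ11,Optimism and good relationships and healthy habits help maintain mental health,knowledge,yes_no,positive
MHKQ12,A family history of mental illness raises the risk of mental health problems,knowledge,yes_no,positive
MHKQ13,Adolescents' psychological problems do not affect academic performance,knowledge,yes_no,positive
MHKQ14,Middle-aged and elderly people rarely develop psychological problems,knowledge,yes_no,positive
MHKQ15,People with poor personality traits are more prone to psychological problems,knowledge,yes_no,positive
MHKQ16,High stress or major life events can easily trigger psychological problems,knowledge,yes_no,positive
MHKQ17,Awareness of World Mental Health Day,knowledge,know_dontknow,positive
MHKQ18,Awareness of the International Day Against Drug Abuse,knowledge,know_dontknow,positive
MHKQ19,Awareness of World Suicide Prevention Day,knowledge,know_dontknow,positive
MHKQ20,Awareness of World Sleep Day,knowledge,know_dontknow,positive
Stigma1,Most people would accept a former psychiatric inpatient as a close friend,stigma,likert4,positive
Stigma2,Most people see someone hospitalized for mental illness as dangerous,stigma,likert4,positive
Stigma3,Most people consider a former psychiatric inpatient as trustworthy as anyone,stigma,likert4,positive
Stigma4,Most people would accept a fully recovered person as a schoolteacher,stigma,likert4,positive
Stigma5,Most employers will not hire a person hospitalized for mental illness,stigma,likert4,positive
Stigma6,Most people think less of a person after psychiatric hospitalization,stigma,likert4,positive
Stigma7,Most people would be willing to marry a former psychiatric patient,stigma,likert4,positive
Stigma8,Most employers will hire a qualified former psychiatric inpatient,stigma,likert4,positive
Stigma9,Most people see entering a psychiatric hospital as personal failure,stigma,likert4,positive
Stigma10,Most people will not let a former psychiatric inpatient care for their children,stigma,likert4,positive
Stigma11,Most people in the community would treat a former inpatient like anyone else,stigma,likert4,positive
Stigma12,Most young people would be reluctant to date someone hospitalized for mental illness,stigma,likert4,positive
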